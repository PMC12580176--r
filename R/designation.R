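# WHO/IUIS allergen nomenclature: "Gad m 1" names the allergen (genus
# abbreviation, species abbreviation, allergen number); isoallergens append
# two digits ("Clu h 1.01") and variants two more ("Gad m 1.0101").

#' Parse a WHO/IUIS allergen designation
#'
#' Splits a designation such as `"Gad m 1.0101"` into the allergen base name,
#' the two-digit isoallergen code and the two-digit variant code. Input is
#' normalized first: whitespace is collapsed, the genus token is capitalized
#' and the species token(s) lower-cased, so `"gad  M 1.0101"` parses the same
#' as `"Gad m 1.0101"`.
#'
#' @param name Character scalar, e.g. `"Gad m 1.0101"`, `"Clu h 1.01"`,
#'   `"Sar sa 1"`.
#' @return A list of class `"allergen_designation"` with elements
#'   `allergen_base` (e.g. `"Gad m 1"`), `isoallergen_code` (two-digit string
#'   or `NA`) and `variant_code` (two-digit string or `NA`). A variant code is
#'   only ever present together with an isoallergen code.
#' @examples
#' parse_allergen_designation("Gad m 1.0101")
#' parse_allergen_designation("Clu h 1.01")
#' @export
parse_allergen_designation <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    stop("designation must be a non-empty character scalar", call. = FALSE)
  }
  s <- normalize_designation_text(name)
  tokens <- strsplit(s, " ", fixed = TRUE)[[1]]
  if (length(tokens) < 3L) {
    stop("malformed allergen designation '", name,
         "': expected genus, species and allergen-number tokens", call. = FALSE)
  }
  last <- tokens[length(tokens)]
  # last token: allergen number with optional .NN or .NNNN suffix
  m <- regmatches(last, regexec("^([0-9]+)(?:\\.([0-9]+))?$", last))[[1]]
  if (length(m) == 0L) {
    stop("malformed allergen designation '", name,
         "': no allergen-number token in '", last, "'", call. = FALSE)
  }
  number <- m[2]
  digits <- m[3]
  iso <- NA_character_
  var <- NA_character_
  if (nzchar(digits)) {
    if (nchar(digits) == 2L) {
      iso <- digits
    } else if (nchar(digits) == 4L) {
      iso <- substr(digits, 1L, 2L)
      var <- substr(digits, 3L, 4L)
    } else {
      stop("malformed allergen designation '", name,
           "': isoallergen/variant suffix '.", digits,
           "' must have 2 or 4 digits", call. = FALSE)
    }
  }
  genus <- tokens[1]
  species <- tokens[-c(1L, length(tokens))]
  if (!grepl("^[A-Z][a-z]*$", genus)) {
    stop("malformed allergen designation '", name,
         "': bad genus token '", genus, "'", call. = FALSE)
  }
  if (length(species) < 1L || length(species) > 2L ||
      !all(grepl("^[a-z]+$", species))) {
    stop("malformed allergen designation '", name,
         "': species abbreviation must be 1-2 lowercase tokens, got '",
         paste(species, collapse = " "), "'", call. = FALSE)
  }
  structure(
    list(
      allergen_base = paste(c(genus, species, number), collapse = " "),
      isoallergen_code = iso,
      variant_code = var
    ),
    class = "allergen_designation"
  )
}

normalize_designation_text <- function(s) {
  s <- stringr::str_squish(s)
  tokens <- strsplit(s, " ", fixed = TRUE)[[1]]
  if (length(tokens) >= 1L) {
    g <- tokens[1]
    tokens[1] <- paste0(toupper(substr(g, 1L, 1L)), tolower(substr(g, 2L, nchar(g))))
  }
  if (length(tokens) >= 3L) {
    mid <- seq(2L, length(tokens) - 1L)
    tokens[mid] <- tolower(tokens[mid])
  }
  paste(tokens, collapse = " ")
}

#' Format an allergen designation back to its canonical string
#'
#' Inverse of [parse_allergen_designation()]: `format_allergen_designation(
#' parse_allergen_designation(s))` equals the normalized form of `s`.
#'
#' @param d An `allergen_designation` object.
#' @return Character scalar, e.g. `"Gad m 1.0101"`.
#' @export
format_allergen_designation <- function(d) {
  stopifnot(inherits(d, "allergen_designation"))
  out <- d$allergen_base
  if (!is.na(d$isoallergen_code)) {
    out <- paste0(out, ".", d$isoallergen_code)
    if (!is.na(d$variant_code)) out <- paste0(out, d$variant_code)
  }
  out
}

#' @export
print.allergen_designation <- function(x, ...) {
  cat("<allergen designation> ", format_allergen_designation(x), "\n", sep = "")
  invisible(x)
}

#' Normalize a designation string, or return NA for unparseable input
#'
#' @param name Character vector of designation strings (may contain `NA`).
#' @return Character vector of canonical designation strings; `NA` where the
#'   input was `NA`.
#' @export
normalize_designation <- function(name) {
  vapply(name, function(s) {
    if (is.na(s)) return(NA_character_)
    format_allergen_designation(parse_allergen_designation(s))
  }, character(1), USE.NAMES = FALSE)
}
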