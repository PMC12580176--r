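# Linear B-cell epitope sets and mismatch-tolerant mapping onto protein
# sequences. An epitope "maps" to a sequence when some ungapped window of
# the sequence is within a given Hamming distance of the epitope peptide
# (substitutions only, no indels). Counts are per distinct epitope peptide:
# an epitope matching several windows still counts once.

#' Build a filtered epitope set
#'
#' Reduces a raw epitope export to the records used for mapping: linear
#' epitopes of one assay polarity, deduplicated by peptide string (assay ids
#' of collapsed duplicates are merged). Records of the other polarity are
#' rejected with a message; conformational records are dropped.
#'
#' @param records A tibble with columns `peptide`, `polarity`
#'   (`"positive"`/`"negative"`), `type` (`"linear"`/`"conformational"`) and
#'   optionally `species`, `assay_id`.
#' @param polarity Which assay polarity this set represents.
#' @param restrict_species Optional character vector; keep only records
#'   whose `species` is listed.
#' @return A list of class `"epitope_set"` with `polarity` and `records`, a
#'   tibble of distinct peptides with merged `assay_ids` and `species`.
#' @export
build_epitope_set <- function(records, polarity = c("positive", "negative"),
                              restrict_species = NULL) {
  polarity <- match.arg(polarity)
  records <- tibble::as_tibble(records)
  if (!"assay_id" %in% names(records)) records$assay_id <- NA_character_
  if (!"species" %in% names(records)) records$species <- NA_character_
  n_other <- sum(records$polarity != polarity)
  if (n_other > 0L) {
    message("dropping ", n_other, " record(s) of polarity other than '",
            polarity, "'")
    records <- records[records$polarity == polarity, , drop = FALSE]
  }
  records <- records[records$type == "linear", , drop = FALSE]
  if (!is.null(restrict_species)) {
    records <- records[records$species %in% restrict_species, , drop = FALSE]
  }
  records$peptide <- toupper(records$peptide)
  bad <- nchar(records$peptide) < 4L
  if (any(bad)) {
    stop("epitope peptides must be at least 4 residues long (",
         paste(records$peptide[bad], collapse = ", "), ")", call. = FALSE)
  }
  dedup <- records |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      species = paste(sort(unique(stats::na.omit(.data$species))), collapse = ";"),
      assay_ids = paste(sort(unique(stats::na.omit(.data$assay_id))), collapse = ";"),
      .groups = "drop"
    )
  if (nrow(dedup) == 0L) warning("epitope set is empty after filtering")
  structure(list(polarity = polarity, records = dedup), class = "epitope_set")
}

#' @export
print.epitope_set <- function(x, ...) {
  cat("<epitope set> ", nrow(x$records), " distinct linear ", x$polarity,
      " epitope(s)\n", sep = "")
  invisible(x)
}

#' Find mismatch-tolerant matches of a peptide in a sequence
#'
#' Scans every ungapped window of the sequence of the peptide's length and
#' reports those within `max_mismatches` substitutions (Hamming distance;
#' indels are not allowed inside a window). Nonstandard residues — anything
#' outside the 20 canonical codes, such as `X` — never match, not even
#' another `X`. Comparison is case-insensitive.
#'
#' @param peptide Epitope peptide string.
#' @param sequence Protein sequence string.
#' @param max_mismatches Maximum substitutions allowed (>= 0).
#' @return A tibble with `start` (1-based window start, ascending) and
#'   `mismatches`; zero rows when the peptide is longer than the sequence or
#'   no window qualifies.
#' @export
find_matches <- function(peptide, sequence, max_mismatches = 0L) {
  stopifnot(max_mismatches >= 0L)
  p <- strsplit(toupper(peptide), "")[[1]]
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(p)
  n <- length(s)
  empty <- tibble::tibble(start = integer(), mismatches = integer())
  if (L == 0L || L > n) return(empty)
  n_win <- n - L + 1L
  mm <- integer(n_win)
  p_canon <- p %in% CANONICAL_AA
  s_canon <- s %in% CANONICAL_AA
  for (j in seq_len(L)) {
    win <- j:(j + n_win - 1L)
    matched <- p_canon[j] & s_canon[win] & s[win] == p[j]
    mm <- mm + !matched
  }
  hit <- which(mm <= max_mismatches)
  tibble::tibble(start = hit, mismatches = mm[hit])
}

#' Count distinct epitopes mapping to a sequence
#'
#' @param set An `"epitope_set"`.
#' @param sequence Protein sequence string.
#' @param max_mismatches Maximum substitutions allowed per window.
#' @return Number of distinct epitope peptides with at least one qualifying
#'   window; multiple windows for one epitope count once.
#' @export
count_epitope_hits <- function(set, sequence, max_mismatches = 0L) {
  stopifnot(inherits(set, "epitope_set"))
  sum(vapply(set$records$peptide, function(p) {
    nrow(find_matches(p, sequence, max_mismatches)) > 0L
  }, logical(1)))
}

#' Per-sequence epitope count statistics
#'
#' Computes, for every sequence, the four mapping statistics: distinct
#' positive epitopes matching exactly (`n_positive`), positive epitopes
#' matching with up to `max_mismatches` substitutions (`n_positive_2m`), and
#' the same two counts for the negative set (`n_negative`,
#' `n_negative_2m`). Optional externally supplied annotation values
#' (percent identity over an 80-aa linear window and over the 3D epitope
#' surface, as reported by a structure-aware prediction tool) are carried
#' through unmodified.
#'
#' @param sequences Named character vector of protein sequences (names must
#'   be unique).
#' @param pos_set,neg_set `"epitope_set"` objects (positive and negative
#'   assay polarity).
#' @param max_mismatches Mismatch allowance for the `_2m` columns
#'   (default 2).
#' @param passthrough Optional tibble with `sequence_id`,
#'   `passthrough_linear80`, `passthrough_3depi`.
#' @return A tibble with one row per sequence: `sequence_id`, `n_positive`,
#'   `n_positive_2m`, `n_negative`, `n_negative_2m`,
#'   `passthrough_linear80`, `passthrough_3depi`.
#' @export
annotate_counts <- function(sequences, pos_set, neg_set, max_mismatches = 2L,
                            passthrough = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- tibble::tibble(
    sequence_id = ids,
    n_positive = vapply(sequences, count_epitope_hits, set = pos_set,
                        max_mismatches = 0L, integer(1), USE.NAMES = FALSE),
    n_positive_2m = vapply(sequences, count_epitope_hits, set = pos_set,
                           max_mismatches = max_mismatches, integer(1),
                           USE.NAMES = FALSE),
    n_negative = vapply(sequences, count_epitope_hits, set = neg_set,
                        max_mismatches = 0L, integer(1), USE.NAMES = FALSE),
    n_negative_2m = vapply(sequences, count_epitope_hits, set = neg_set,
                           max_mismatches = max_mismatches, integer(1),
                           USE.NAMES = FALSE),
    passthrough_linear80 = NA_real_,
    passthrough_3depi = NA_real_
  )
  if (!is.null(passthrough)) {
    idx <- match(rows$sequence_id, passthrough$sequence_id)
    rows$passthrough_linear80 <- passthrough$passthrough_linear80[idx]
    rows$passthrough_3depi <- passthrough$passthrough_3depi[idx]
  }
  rows
}
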