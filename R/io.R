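# Readers/writers for the plain-text exchange formats: catalog TSV, FASTA,
# epitope TSV, and the per-tool misclassification table.

#' Read an allergen catalog from TSV
#'
#' The file must carry the catalog header (see [allergen_catalog()] for the
#' column set); empty fields become `NA`.
#'
#' @param path Path to a tab-separated catalog file.
#' @return A validated catalog tibble.
#' @export
read_catalog <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  for (col in paste0("in_", CATALOG_SOURCES)) {
    raw[[col]] <- toupper(raw[[col]]) %in% c("TRUE", "T", "1", "YES")
  }
  raw$pmids[is.na(raw$pmids)] <- ""
  raw$designation <- normalize_designation(raw$designation)
  raw$sequence <- toupper(raw$sequence)
  validate_catalog(raw[catalog_columns()])
}

#' Write an allergen catalog to TSV
#'
#' @param entries A catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(entries, path) {
  validate_catalog(entries)
  readr::write_tsv(entries, path, progress = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an (uncompressed) amino acid FASTA file.
#' @return A named character vector of upper-cased residue strings; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Extract FASTA records from a catalog
#'
#' Record ids are the normalized designation where assigned, otherwise the
#' primary accession; only entries with a sequence are emitted.
#'
#' @param entries A catalog tibble.
#' @return Named character vector of sequences.
#' @export
catalog_sequences <- function(entries) {
  validate_catalog(entries)
  keep <- !is.na(entries$sequence)
  entries <- entries[keep, , drop = FALSE]
  seqs <- entries$sequence
  names(seqs) <- entry_key(entries)
  seqs
}

#' Read an epitope record table
#'
#' Expects the column layout of an epitope-database export reduced to the
#' relevant fields: `peptide`, `polarity` (`positive`/`negative`), `type`
#' (`linear`/`conformational`), `species`, `assay_id`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of raw epitope records (not yet filtered; see
#'   [build_epitope_set()]).
#' @export
read_epitope_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = c("", "NA"), progress = FALSE)
}

#' Read the per-tool misclassification table
#'
#' A small table recording, for each prediction tool, the catalog entries it
#' misclassified as non-allergen and those it rejected for nonstandard
#' residues; columns `tool`, `entry`, `reason`
#' (`misclassified`/`nonstandard`).
#'
#' @param path Path to the TSV; defaults to the copy shipped with the
#'   package.
#' @return A tibble.
#' @export
read_tool_misclassifications <- function(path = system.file(
    "extdata", "tool_misclassifications.tsv", package = "allerpv")) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' Sensitivity of each prediction tool from its misclassification list
#'
#' @param misclass A tibble from [read_tool_misclassifications()].
#' @param n_total Number of known allergens every tool was scored on.
#' @return A tibble with `tool`, `n_detected` and `sensitivity` (percent,
#'   one decimal), sorted by decreasing sensitivity.
#' @export
tool_sensitivities <- function(misclass, n_total = 79L) {
  tools <- unique(misclass$tool)
  rows <- lapply(tools, function(tl) {
    sub <- misclass[misclass$tool == tl, , drop = FALSE]
    out <- outcomes_from_misclassification(
      misclassified = sub$entry[sub$reason == "misclassified"],
      nonstandard = sub$entry[sub$reason == "nonstandard"],
      n_total = n_total
    )
    tibble::tibble(tool = tl, n_detected = sum(out$detected),
                   sensitivity = compute_sensitivity(out))
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$sensitivity))
}
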