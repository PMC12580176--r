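# Catalog of isoallergen/variant entries compiled from the four allergen
# databases (WHO/IUIS, AllergenOnline, COMPARE, Allergome). An entry catalog
# is a plain tibble with one row per entry and a fixed column set; all
# curation operations take and return such tibbles.

CATALOG_SOURCES <- c("whoiuis", "allergenonline", "compare", "allergome")
CATALOG_SOURCE_LABELS <- c(
  whoiuis = "WHO/IUIS", allergenonline = "AllergenOnline",
  compare = "COMPARE", allergome = "Allergome"
)
ACCESSION_KINDS <- c("uniprot", "refseq", "genbank_protein", "pdb")
CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

catalog_columns <- function() {
  c("designation", "biochemical_name", "species_latin", "species_common",
    "uniprot", "refseq", "genbank_protein", "genbank_nucleotide", "pdb",
    "sequence", "completeness",
    "in_whoiuis", "in_allergenonline", "in_compare", "in_allergome",
    "pmids")
}

#' Construct an allergen entry catalog
#'
#' Builds the canonical catalog tibble from per-entry vectors, normalizing
#' designations and upper-casing sequences, and validates the entry
#' invariants: an entry with `completeness == "absent"` carries no sequence,
#' every entry has a designation or at least one accession, and every entry
#' is flagged in at least one source database.
#'
#' @param designation Character, WHO/IUIS designation or `NA` for unassigned
#'   entries.
#' @param biochemical_name Character, e.g. `"beta-parvalbumin"`.
#' @param species_latin,species_common Character.
#' @param uniprot,refseq,genbank_protein,genbank_nucleotide,pdb Character
#'   accessions (`NA` where absent).
#' @param sequence Character residue string or `NA`.
#' @param completeness One of `"complete"`, `"partial"`, `"absent"` per entry.
#' @param in_whoiuis,in_allergenonline,in_compare,in_allergome Logical source
#'   presence flags.
#' @param pmids Character, semicolon-separated PubMed ids (`""` if none).
#' @return A tibble with one row per entry.
#' @export
allergen_catalog <- function(designation = NA_character_,
                             biochemical_name,
                             species_latin,
                             species_common = NA_character_,
                             uniprot = NA_character_,
                             refseq = NA_character_,
                             genbank_protein = NA_character_,
                             genbank_nucleotide = NA_character_,
                             pdb = NA_character_,
                             sequence = NA_character_,
                             completeness = "complete",
                             in_whoiuis = FALSE,
                             in_allergenonline = FALSE,
                             in_compare = FALSE,
                             in_allergome = FALSE,
                             pmids = "") {
  entries <- tibble::tibble(
    designation = normalize_designation(as.character(designation)),
    biochemical_name = as.character(biochemical_name),
    species_latin = as.character(species_latin),
    species_common = as.character(species_common),
    uniprot = as.character(uniprot),
    refseq = as.character(refseq),
    genbank_protein = as.character(genbank_protein),
    genbank_nucleotide = as.character(genbank_nucleotide),
    pdb = as.character(pdb),
    sequence = toupper(as.character(sequence)),
    completeness = as.character(completeness),
    in_whoiuis = as.logical(in_whoiuis),
    in_allergenonline = as.logical(in_allergenonline),
    in_compare = as.logical(in_compare),
    in_allergome = as.logical(in_allergome),
    pmids = as.character(pmids)
  )
  validate_catalog(entries)
}

#' Validate a catalog tibble
#'
#' @param entries A catalog tibble (see [allergen_catalog()]).
#' @return `entries`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_catalog <- function(entries) {
  missing_cols <- setdiff(catalog_columns(), names(entries))
  if (length(missing_cols) > 0L) {
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !entries$completeness %in% c("complete", "partial", "absent")
  if (any(bad)) {
    stop("invalid completeness value(s): ",
         paste(unique(entries$completeness[bad]), collapse = ", "),
         call. = FALSE)
  }
  seq_absent <- entries$completeness == "absent" & !is.na(entries$sequence)
  if (any(seq_absent)) {
    stop("entries flagged completeness 'absent' must not carry a sequence (rows ",
         paste(which(seq_absent), collapse = ", "), ")", call. = FALSE)
  }
  has_acc <- Reduce(`|`, lapply(entries[ACCESSION_KINDS], function(x) !is.na(x)))
  anonymous <- is.na(entries$designation) & !has_acc
  if (any(anonymous)) {
    stop("entries must have a designation or at least one accession (rows ",
         paste(which(anonymous), collapse = ", "), ")", call. = FALSE)
  }
  src <- entries[paste0("in_", CATALOG_SOURCES)]
  no_src <- !Reduce(`|`, src)
  if (any(no_src)) {
    stop("entries must be flagged in at least one source database (rows ",
         paste(which(no_src), collapse = ", "), ")", call. = FALSE)
  }
  entries
}

#' Select an entry's primary accession
#'
#' Accession priority follows the curation rule used when retrieving
#' sequences: UniProt first, then RefSeq, then GenBank protein, then PDB.
#'
#' @param entry A single catalog row (one-row tibble or named list).
#' @return A list with `kind` (one of `"uniprot"`, `"refseq"`,
#'   `"genbank_protein"`, `"pdb"`) and `accession`.
#' @export
select_primary_accession <- function(entry) {
  for (kind in ACCESSION_KINDS) {
    acc <- entry[[kind]]
    if (length(acc) == 1L && !is.na(acc)) {
      return(list(kind = kind, accession = acc))
    }
  }
  stop("entry has no accession", call. = FALSE)
}

entry_key <- function(entries) {
  ifelse(
    !is.na(entries$designation),
    entries$designation,
    vapply(seq_len(nrow(entries)), function(i) {
      select_primary_accession(entries[i, ])$accession
    }, character(1))
  )
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_character_ else x[[1L]]
}

#' Deduplicate catalog entries
#'
#' Collapses rows that describe the same entry: rows sharing a designation
#' (or, for unassigned entries, the same primary accession) are merged into
#' one. Source flags are OR-ed, PubMed ids unioned, accessions filled from
#' the first row that provides each kind, and completeness takes the best
#' available state (`complete` over `partial` over `absent`). Two rows under
#' one key with different non-missing sequences are a curation conflict and
#' raise an error rather than a silent pick.
#'
#' @param entries A catalog tibble.
#' @return The deduplicated catalog, one row per key, in first-appearance
#'   order.
#' @export
deduplicate_entries <- function(entries) {
  validate_catalog(entries)
  if (nrow(entries) == 0L) return(entries)
  key <- entry_key(entries)
  merged <- lapply(unique(key), function(k) {
    grp <- entries[key == k, , drop = FALSE]
    seqs <- unique(grp$sequence[!is.na(grp$sequence)])
    if (length(seqs) > 1L) {
      stop("conflicting sequences for entry key '", k,
           "': sources disagree and must be curated manually", call. = FALSE)
    }
    comp_rank <- c(complete = 1L, partial = 2L, absent = 3L)
    pmids <- unique(unlist(strsplit(grp$pmids[!is.na(grp$pmids)], ";", fixed = TRUE)))
    pmids <- pmids[nzchar(pmids)]
    tibble::tibble(
      designation = first_non_na(grp$designation),
      biochemical_name = first_non_na(grp$biochemical_name),
      species_latin = first_non_na(grp$species_latin),
      species_common = first_non_na(grp$species_common),
      uniprot = first_non_na(grp$uniprot),
      refseq = first_non_na(grp$refseq),
      genbank_protein = first_non_na(grp$genbank_protein),
      genbank_nucleotide = first_non_na(grp$genbank_nucleotide),
      pdb = first_non_na(grp$pdb),
      sequence = if (length(seqs) == 1L) seqs else NA_character_,
      completeness = names(comp_rank)[min(comp_rank[grp$completeness])],
      in_whoiuis = any(grp$in_whoiuis),
      in_allergenonline = any(grp$in_allergenonline),
      in_compare = any(grp$in_compare),
      in_allergome = any(grp$in_allergome),
      pmids = paste(sort(pmids), collapse = ";")
    )
  })
  dplyr::bind_rows(merged)
}

#' Keep only entries with a complete amino acid sequence
#'
#' Downstream analyses (identity summaries, tool sensitivity, epitope
#' mapping) use only entries whose full sequence is available; completeness
#' is catalog metadata, never inferred from sequence content.
#'
#' @param entries A catalog tibble.
#' @return The subset with `completeness == "complete"`, order preserved.
#' @export
filter_complete <- function(entries) {
  validate_catalog(entries)
  entries[entries$completeness == "complete", , drop = FALSE]
}

#' Count entries per source-database combination
#'
#' Tabulates, over a deduplicated catalog, how many entries carry each
#' combination of source flags — the numbers behind a four-set Venn diagram.
#'
#' @param entries A deduplicated catalog tibble.
#' @return A tibble with `combination` (e.g.
#'   `"WHO/IUIS+AllergenOnline+COMPARE+Allergome"`) and `n`; the `n` column
#'   sums to `nrow(entries)`.
#' @export
database_overlap <- function(entries) {
  validate_catalog(entries)
  flags <- as.matrix(entries[paste0("in_", CATALOG_SOURCES)])
  combo <- apply(flags, 1L, function(row) {
    paste(CATALOG_SOURCE_LABELS[CATALOG_SOURCES[row]], collapse = "+")
  })
  out <- dplyr::count(tibble::tibble(combination = combo), .data$combination,
                      name = "n")
  dplyr::arrange(out, dplyr::desc(.data$n), .data$combination)
}

#' Summarize the catalog per biochemical family
#'
#' For each biochemical name, counts total entries, entries carrying a
#' WHO/IUIS-assigned designation vs unassigned, and the number of distinct
#' species — the accounting of the per-family summary table.
#'
#' @param entries A deduplicated, complete-filtered catalog tibble.
#' @return A tibble with columns `biochemical_name`, `total`,
#'   `iuis_assigned`, `unassigned`, `n_species`, sorted by decreasing
#'   `total`.
#' @export
summarize_families <- function(entries) {
  validate_catalog(entries)
  entries |>
    dplyr::group_by(.data$biochemical_name) |>
    dplyr::summarise(
      total = dplyr::n(),
      iuis_assigned = sum(!is.na(.data$designation)),
      unassigned = sum(is.na(.data$designation)),
      n_species = dplyr::n_distinct(.data$species_latin),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$biochemical_name)
}

#' Percent sensitivity of an allergenicity prediction tool
#'
#' All scored entries are known allergens, so sensitivity is simply the
#' percentage flagged as allergen. Sequences a tool cannot process (absent
#' or nonstandard residues such as X) are scored as non-allergens, i.e. as
#' missed.
#'
#' @param outcomes A tibble with logical columns `detected` and
#'   `rejected_nonstandard` (one row per known allergen submitted).
#' @return Sensitivity in percent, rounded half-up to one decimal.
#' @export
compute_sensitivity <- function(outcomes) {
  if (nrow(outcomes) == 0L) stop("no outcomes to score", call. = FALSE)
  stopifnot(is.logical(outcomes$detected),
            is.logical(outcomes$rejected_nonstandard))
  if (any(outcomes$rejected_nonstandard & outcomes$detected)) {
    stop("a sequence rejected for nonstandard residues cannot be detected",
         call. = FALSE)
  }
  round_half_up(100 * sum(outcomes$detected) / nrow(outcomes), 1L)
}

#' Does a sequence contain nonstandard residues?
#'
#' Nonstandard means any character outside the 20 canonical one-letter amino
#' acid codes; `X` therefore qualifies.
#'
#' @param sequence Character vector of residue strings.
#' @return Logical vector.
#' @export
has_nonstandard_residues <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    any(!strsplit(s, "")[[1]] %in% CANONICAL_AA)
  }, logical(1), USE.NAMES = FALSE)
}

#' Expand per-tool misclassification lists into outcome tables
#'
#' Prediction-tool results are recorded as the (short) list of entries each
#' tool missed, plus the entries it could not process because of nonstandard
#' residues; every other entry in the evaluated set counts as detected.
#'
#' @param misclassified Character vector of entry ids missed by the tool.
#' @param nonstandard Character vector of entry ids rejected for nonstandard
#'   residues.
#' @param n_total Total number of known allergens submitted.
#' @param all_ids Optional character vector of all entry ids (length
#'   `n_total`); placeholder ids are generated when omitted.
#' @return An outcome tibble suitable for [compute_sensitivity()].
#' @export
outcomes_from_misclassification <- function(misclassified, nonstandard,
                                            n_total, all_ids = NULL) {
  misclassified <- setdiff(misclassified, nonstandard)
  n_named <- length(misclassified) + length(nonstandard)
  if (n_named > n_total) {
    stop("more misclassified entries than entries scored", call. = FALSE)
  }
  if (is.null(all_ids)) {
    all_ids <- c(misclassified, nonstandard,
                 sprintf("detected_%03d", seq_len(n_total - n_named)))
  }
  if (length(all_ids) != n_total) {
    stop("all_ids must have length n_total", call. = FALSE)
  }
  tibble::tibble(
    entry_key = all_ids,
    detected = !all_ids %in% c(misclassified, nonstandard),
    rejected_nonstandard = all_ids %in% nonstandard
  )
}

# Round half away from zero (what a spreadsheet prints), not banker's
# rounding: 83.544 -> 83.5, 89.873 -> 89.9.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
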