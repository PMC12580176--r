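# Pairwise percent identity between catalog sequences, and the per-family
# summary rule (mean +/- SD (min-max) excluding self-comparisons and 100%
# pairs; a single surviving pair is reported without SD).
#
# Identities come from affine-gap global (Needleman-Wunsch) alignment with
# BLOSUM62, gap open 10, gap extend 0.5 — ClustalW-style parameters used as
# a reproducible stand-in for MSA-derived identity matrices. The denominator
# is the number of alignment columns where both sequences hold a residue.

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, delegated to
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Residue strings (canonical amino acids, `X` allowed).
#' @param substitution_matrix Name or matrix of substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A list of class `"pairwise_alignment"` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(a)),
    subject = Biostrings::AAString(toupper(b)),
    type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open,
    gapExtension = gap_extend
  )
  out <- list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
  stopifnot(nchar(out$aligned_a) == nchar(out$aligned_b))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise alignment> score ", format(x$score), "\n",
      x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identity is counted over columns where both sequences hold a residue
#' (gapless columns of the pair); `X` never counts as identical, even
#' against another `X`.
#'
#' @param aln A `"pairwise_alignment"` from [global_align()].
#' @return Percent identity (0-100), unrounded.
#' @export
percent_identity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  ident <- both & ca == cb & ca %in% CANONICAL_AA
  100 * sum(ident) / sum(both)
}

#' Pairwise percent identity between two sequences
#'
#' Convenience wrapper: [global_align()] then [percent_identity()].
#'
#' @inheritParams global_align
#' @return Percent identity (0-100).
#' @export
pairwise_identity <- function(a, b, ...) {
  percent_identity(global_align(a, b, ...))
}

#' All pairwise identities within a set of sequences
#'
#' @param seqs Named character vector of residue strings.
#' @param ... Passed to [global_align()].
#' @return A long-format tibble with `id_a`, `id_b`, `identity` over all
#'   unordered pairs.
#' @export
pairwise_identity_table <- function(seqs, ...) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_len(n))
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  pairs <- utils::combn(n, 2L)
  rows <- apply(pairs, 2L, function(ij) {
    tibble::tibble(
      id_a = names(seqs)[ij[1]],
      id_b = names(seqs)[ij[2]],
      identity = pairwise_identity(seqs[[ij[1]]], seqs[[ij[2]]], ...)
    )
  })
  dplyr::bind_rows(rows)
}

#' Group percent-identity summary
#'
#' Summarises all unordered pairwise identities within one allergen family:
#' identities are rounded to one decimal, pairs at exactly 100% are dropped,
#' and the mean, sample SD, min and max of the remainder are reported. When
#' only one informative pair remains (in particular for two-sequence
#' groups), the single value is reported without an SD.
#'
#' @param seqs Character vector of at least two residue strings.
#' @param ... Passed to [global_align()].
#' @return A list with `mean`, `sd` (`NA` when a single pair was used),
#'   `min`, `max`, `n_pairs_used`.
#' @export
group_identity_summary <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  ids <- round_half_up(pairwise_identity_table(seqs, ...)$identity, 1L)
  ids <- ids[ids < 100]
  if (length(ids) == 0L) {
    stop("no informative pairs: all pairwise identities are 100%", call. = FALSE)
  }
  list(
    mean = mean(ids),
    sd = if (length(ids) == 1L) NA_real_ else stats::sd(ids),
    min = min(ids),
    max = max(ids),
    n_pairs_used = length(ids)
  )
}

#' Per-family identity summary table for a catalog
#'
#' Applies [group_identity_summary()] to every biochemical family with at
#' least two sequenced entries; single-entry families are reported with all
#' summary fields `NA`.
#'
#' @param entries A deduplicated, complete-filtered catalog tibble.
#' @param ... Passed to [global_align()].
#' @return A tibble with one row per biochemical family: `biochemical_name`,
#'   `n_sequences`, `mean`, `sd`, `min`, `max`, `n_pairs_used`.
#' @export
family_identity_table <- function(entries, ...) {
  validate_catalog(entries)
  fams <- unique(entries$biochemical_name)
  rows <- lapply(fams, function(f) {
    seqs <- entries$sequence[entries$biochemical_name == f & !is.na(entries$sequence)]
    base <- tibble::tibble(biochemical_name = f, n_sequences = length(seqs))
    if (length(seqs) < 2L) {
      return(dplyr::mutate(base, mean = NA_real_, sd = NA_real_,
                           min = NA_real_, max = NA_real_, n_pairs_used = 0L))
    }
    s <- group_identity_summary(seqs, ...)
    dplyr::mutate(base, mean = s$mean, sd = s$sd, min = s$min, max = s$max,
                  n_pairs_used = s$n_pairs_used)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$n_sequences))
}
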