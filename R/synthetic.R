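# Synthetic panels with planted-epitope ground truth. The generator
# emulates the statistical structure the downstream analysis assumes: an
# epitope-rich allergenic class (beta-parvalbumin-like) whose sequences
# carry several planted positive epitopes with at most two injected
# substitutions each, and an epitope-poor class (alpha-parvalbumin-like)
# whose rare plantings are mutated beyond the two-mismatch horizon.

#' Configuration for the synthetic panel generator
#'
#' Defaults mirror the annotated parvalbumin panel: 11 allergenic vs 9
#' less/non-allergenic sequences of 109 residues (a typical parvalbumin
#' length), with a library of 30 positive and 20 negative epitopes of 8-16
#' residues. Allergenic sequences receive `Poisson(plant_rate_allergenic)`
#' planted positive epitopes (at least `min_plant_allergenic`, at most what
#' fits without overlap), each copy mutated at 0..`plant_mismatch_max`
#' positions; less/non-allergenic sequences receive 0 or 1 planting mutated
#' at 3-4 positions, below the two-mismatch detection horizon.
#'
#' @param n_allergenic,n_nonallergenic Class sizes.
#' @param seq_length Sequence length in residues.
#' @param n_pos_epitopes,n_neg_epitopes Epitope library sizes.
#' @param epitope_len_range Length 2 integer vector, inclusive peptide
#'   length range.
#' @param plant_rate_allergenic Mean planted epitopes per allergenic
#'   sequence.
#' @param min_plant_allergenic Guaranteed minimum plantings per allergenic
#'   sequence, so class labels are consistent with planting by construction.
#' @param plant_mismatch_max Maximum substitutions injected per planted copy
#'   (<= 2 keeps plantings within the two-mismatch mapping horizon).
#' @param class_divergence Per-site substitution probability between the
#'   shared root and each class ancestor. The two classes are generated as
#'   homologous lineages (like beta- vs alpha-parvalbumins), not unrelated
#'   random strings, so distance-based trees over the panel are meaningful.
#' @param within_class_divergence Per-site substitution probability between
#'   a class ancestor and each of its sequences.
#' @param background Residue sampling weights; default uniform over the 20
#'   canonical residues. A composition table (named numeric vector over the
#'   residue alphabet) may be supplied for realism.
#' @param seed Integer seed; all outputs are reproducible from the config.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_allergenic = 11L,
                             n_nonallergenic = 9L,
                             seq_length = 109L,
                             n_pos_epitopes = 30L,
                             n_neg_epitopes = 20L,
                             epitope_len_range = c(8L, 16L),
                             plant_rate_allergenic = 5,
                             min_plant_allergenic = 2L,
                             plant_mismatch_max = 2L,
                             class_divergence = 0.3,
                             within_class_divergence = 0.1,
                             background = NULL,
                             seed = 1L) {
  stopifnot(n_allergenic >= 1L, n_nonallergenic >= 1L, seq_length > 0L,
            length(epitope_len_range) == 2L,
            epitope_len_range[1] >= 4L,
            epitope_len_range[2] <= seq_length,
            epitope_len_range[1] <= epitope_len_range[2],
            plant_rate_allergenic >= 0,
            min_plant_allergenic >= 0L,
            plant_mismatch_max >= 0L, plant_mismatch_max <= 2L,
            class_divergence >= 0, class_divergence < 1,
            within_class_divergence >= 0, within_class_divergence < 1)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), CANONICAL_AA)
  }
  structure(
    list(n_allergenic = as.integer(n_allergenic),
         n_nonallergenic = as.integer(n_nonallergenic),
         seq_length = as.integer(seq_length),
         n_pos_epitopes = as.integer(n_pos_epitopes),
         n_neg_epitopes = as.integer(n_neg_epitopes),
         epitope_len_range = as.integer(epitope_len_range),
         plant_rate_allergenic = plant_rate_allergenic,
         min_plant_allergenic = as.integer(min_plant_allergenic),
         plant_mismatch_max = as.integer(plant_mismatch_max),
         class_divergence = class_divergence,
         within_class_divergence = within_class_divergence,
         background = background,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

random_peptide <- function(len, background) {
  paste(sample(names(background), len, replace = TRUE, prob = background),
        collapse = "")
}

#' Generate a random epitope library
#'
#' @param n Number of distinct peptides (>= 1).
#' @param len_range Inclusive peptide length range.
#' @param seed Integer seed.
#' @param polarity Polarity tag for the resulting set.
#' @param background Residue sampling weights (default uniform).
#' @return An `"epitope_set"` of `n` distinct random peptides with lengths
#'   uniform in `len_range`.
#' @export
generate_epitope_library <- function(n, len_range = c(8L, 16L), seed = 1L,
                                     polarity = "positive",
                                     background = NULL) {
  stopifnot(n >= 1L)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), CANONICAL_AA)
  }
  capacity <- sum(length(background)^(len_range[1]:len_range[2]))
  if (n > capacity) {
    stop("cannot generate ", n, " distinct peptides in the requested length range",
         call. = FALSE)
  }
  peptides <- withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      len <- sample(len_range[1]:len_range[2], 1L)
      out <- unique(c(out, random_peptide(len, background)))
    }
    out
  })
  build_epitope_set(
    tibble::tibble(peptide = peptides, polarity = polarity, type = "linear",
                   species = "synthetic", assay_id = sprintf("synth_%04d", seq_len(n))),
    polarity = polarity
  )
}

# Sample k non-overlapping intervals of the given lengths inside 1..n;
# returns start positions (in planting order) or NULL if they cannot fit.
place_intervals <- function(lengths, n) {
  if (sum(lengths) > n) return(NULL)
  slack <- n - sum(lengths)
  k <- length(lengths)
  if (k == 0L) return(integer(0))
  # distribute the slack uniformly over the k+1 gaps between intervals
  cuts <- sort(sample.int(slack + k, k)) - seq_len(k)
  ord_starts <- cuts + c(0, cumsum(lengths))[seq_len(k)] + 1L
  ord_starts
}

# substitute each position independently with the given probability
mutate_at_rate <- function(chars, rate, background) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(names(background), chars[i]), 1L)
  }
  chars
}

mutate_copy <- function(peptide, n_mut, background) {
  chars <- strsplit(peptide, "")[[1]]
  if (n_mut == 0L) return(peptide)
  pos <- sample.int(length(chars), n_mut)
  for (i in pos) {
    chars[i] <- sample(setdiff(names(background), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic panel with planted-epitope ground truth
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `"synthetic_dataset"` with `sequences` (named
#'   character vector), `labels` (tibble `sequence_id`, `label`),
#'   `pos_library` / `neg_library` (epitope sets), `truth` (tibble
#'   `sequence_id`, `epitope`, `start`, `injected_mismatches`) and `config`.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  pos_lib <- generate_epitope_library(cfg$n_pos_epitopes, cfg$epitope_len_range,
                                      seed = cfg$seed + 1000L,
                                      polarity = "positive",
                                      background = cfg$background)
  neg_lib <- generate_epitope_library(cfg$n_neg_epitopes, cfg$epitope_len_range,
                                      seed = cfg$seed + 2000L,
                                      polarity = "negative",
                                      background = cfg$background)
  pos_peptides <- pos_lib$records$peptide
  n_total <- cfg$n_allergenic + cfg$n_nonallergenic
  ids <- c(sprintf("allergenic_%02d", seq_len(cfg$n_allergenic)),
           sprintf("nonallergenic_%02d", seq_len(cfg$n_nonallergenic)))
  labels <- c(rep("allergenic", cfg$n_allergenic),
              rep("less_non_allergenic", cfg$n_nonallergenic))
  seqs <- character(n_total)
  truth <- vector("list", n_total)
  withr::with_seed(cfg$seed, {
    root <- strsplit(random_peptide(cfg$seq_length, cfg$background), "")[[1]]
    ancestors <- list(
      allergenic = mutate_at_rate(root, cfg$class_divergence, cfg$background),
      less_non_allergenic = mutate_at_rate(root, cfg$class_divergence,
                                           cfg$background)
    )
    for (i in seq_len(n_total)) {
      seq_chars <- mutate_at_rate(ancestors[[labels[i]]],
                                  cfg$within_class_divergence, cfg$background)
      if (labels[i] == "allergenic") {
        k <- max(stats::rpois(1L, cfg$plant_rate_allergenic), cfg$min_plant_allergenic)
        k <- min(k, length(pos_peptides))
        chosen <- sample(pos_peptides, k)
        # keep the longest prefix of plantings that fits without overlap
        while (sum(nchar(chosen)) > cfg$seq_length && length(chosen) > 0L) {
          chosen <- chosen[-length(chosen)]
        }
        if (length(chosen) < cfg$min_plant_allergenic) {
          stop("cannot fit the guaranteed minimum of ", cfg$min_plant_allergenic,
               " planted epitopes into a sequence of length ", cfg$seq_length,
               call. = FALSE)
        }
        n_mut <- sample.int(cfg$plant_mismatch_max + 1L, length(chosen),
                            replace = TRUE) - 1L
      } else {
        plant <- stats::runif(1L) < 0.5
        chosen <- if (plant) sample(pos_peptides, 1L) else character(0)
        n_mut <- if (plant) sample(3:4, 1L) else integer(0)
      }
      starts <- place_intervals(nchar(chosen), cfg$seq_length)
      if (is.null(starts)) {
        stop("planting cannot fit without overlap into sequence '", ids[i], "'",
             call. = FALSE)
      }
      rows <- vector("list", length(chosen))
      for (j in seq_along(chosen)) {
        copy <- mutate_copy(chosen[j], n_mut[j], cfg$background)
        idx <- starts[j]:(starts[j] + nchar(copy) - 1L)
        seq_chars[idx] <- strsplit(copy, "")[[1]]
        rows[[j]] <- tibble::tibble(sequence_id = ids[i], epitope = chosen[j],
                                    start = starts[j],
                                    injected_mismatches = n_mut[j])
      }
      seqs[i] <- paste(seq_chars, collapse = "")
      truth[[i]] <- dplyr::bind_rows(rows)
    }
  })
  names(seqs) <- ids
  structure(
    list(sequences = seqs,
         labels = tibble::tibble(sequence_id = ids, label = labels),
         pos_library = pos_lib,
         neg_library = neg_lib,
         truth = dplyr::bind_rows(truth),
         config = cfg),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic panel> ", length(x$sequences), " sequences (",
      sum(x$labels$label == "allergenic"), " allergenic), ",
      nrow(x$pos_library$records), " positive / ",
      nrow(x$neg_library$records), " negative epitopes, ",
      nrow(x$truth), " planted copies\n", sep = "")
  invisible(x)
}

#' Verify the planted-epitope ground truth of a synthetic dataset
#'
#' Every planted copy must be recoverable by [find_matches()] at its
#' injected mismatch count: a truth row `(epitope, start, m)` is violated
#' when no hit at `start` with at most `m` mismatches exists in the
#' sequence.
#'
#' @param ds A `"synthetic_dataset"`.
#' @return A list with `n_checked` and `violations` (tibble of failing
#'   truth rows; empty for any correctly generated dataset).
#' @export
verify_truth <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ok <- vapply(seq_len(nrow(ds$truth)), function(i) {
    row <- ds$truth[i, ]
    hits <- find_matches(row$epitope, ds$sequences[[row$sequence_id]],
                         max_mismatches = row$injected_mismatches)
    row$start %in% hits$start
  }, logical(1))
  list(n_checked = nrow(ds$truth),
       violations = ds$truth[!ok, , drop = FALSE])
}

#' Synthetic allergen catalog for a generated panel
#'
#' Wraps the panel sequences in catalog rows (synthetic designations for
#' the allergenic class, accession-only rows for the rest, randomized
#' source flags) so the curation stage of the pipeline can run end to end
#' on generated data. All content is synthetic.
#'
#' @param ds A `"synthetic_dataset"`.
#' @return A catalog tibble.
#' @export
synthetic_catalog <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  n <- length(ds$sequences)
  is_all <- ds$labels$label == "allergenic"
  designation <- ifelse(
    is_all,
    sprintf("Syn a 1.%02d01", cumsum(is_all)),
    NA_character_
  )
  withr::with_seed(ds$config$seed + 3000L, {
    flags <- matrix(stats::runif(4L * n) < 0.6, nrow = n)
    flags[rowSums(flags) == 0L, 1L] <- TRUE
    allergen_catalog(
      designation = designation,
      biochemical_name = ifelse(is_all, "beta-parvalbumin", "alpha-parvalbumin"),
      species_latin = sprintf("Synthspecies %s", letters[(seq_len(n) - 1L) %% 26L + 1L]),
      species_common = "synthetic fish",
      uniprot = sprintf("SYN%05d", seq_len(n)),
      sequence = unname(ds$sequences),
      completeness = "complete",
      in_whoiuis = flags[, 1L],
      in_allergenonline = flags[, 2L],
      in_compare = flags[, 3L],
      in_allergome = flags[, 4L],
      pmids = ""
    )
  })
}
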