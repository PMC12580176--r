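# End-to-end orchestration: catalog curation -> identity summaries ->
# epitope mapping -> thresholding -> annotated phylogeny, writing one run
# directory of plain-text artifacts plus a machine-readable manifest. Every
# stage output is a pure function of (inputs, config, seed), so reruns are
# byte-identical.

#' Pipeline run configuration
#'
#' Either point the pipeline at real exported inputs (`catalog`, `fasta`,
#' `pos_epitopes`, `neg_epitopes` paths) or give a [synthetic_config()] to
#' generate a panel in place.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when real inputs are
#'   given.
#' @param catalog,fasta,pos_epitopes,neg_epitopes Paths to a catalog TSV,
#'   protein FASTA and epitope TSVs (ignored when `synthetic` is given).
#' @param max_mismatches Mismatch allowance for the `_2m` counts.
#' @param threshold `"scan"` to optimize the count threshold, or a fixed
#'   integer (the family-specific default is 4).
#' @param bootstrap Bootstrap replicates for the tree (0 disables supports).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory (created if needed).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(synthetic = NULL, catalog = NULL, fasta = NULL,
                       pos_epitopes = NULL, neg_epitopes = NULL,
                       max_mismatches = 2L, threshold = 4L,
                       bootstrap = 100L, seed = 1L, out_dir = "allerpv_run") {
  if (is.null(synthetic) && (is.null(fasta) || is.null(pos_epitopes) ||
                             is.null(neg_epitopes))) {
    stop("either a synthetic config or real input paths must be supplied",
         call. = FALSE)
  }
  stopifnot(max_mismatches >= 0L)
  structure(
    list(synthetic = synthetic, catalog = catalog, fasta = fasta,
         pos_epitopes = pos_epitopes, neg_epitopes = neg_epitopes,
         max_mismatches = as.integer(max_mismatches), threshold = threshold,
         bootstrap = as.integer(bootstrap), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `synthetic:`
#' mapping is passed to [synthetic_config()].
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  do.call(run_config, y)
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) curation — deduplicate the catalog, keep complete sequences,
#' tabulate database overlap and per-family counts; (2) identity —
#' per-family pairwise percent-identity summaries; (3) mapping — the four
#' per-sequence epitope count statistics; (4) thresholding — threshold
#' scan/fixed threshold, capture rate and Welch test between classes;
#' (5) phylogeny — NJ tree (with bootstrap supports when configured) and
#' the leaf-ordered annotation table. All artifacts are written under
#' `cfg$out_dir` together with `manifest.json`.
#'
#' @param cfg A `"run_config"`.
#' @return Invisibly, a list with the in-memory stage results (`catalog`,
#'   `overlap`, `families`, `identity`, `counts`, `threshold`, `tree`,
#'   `annotation`, `manifest`).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$out_dir, name)

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    ds <- generate_panel(cfg$synthetic)
    catalog <- synthetic_catalog(ds)
    seqs <- ds$sequences
    pos_set <- ds$pos_library
    neg_set <- ds$neg_library
    labels <- ds$labels
    write_fasta_sequences(seqs, out("panel.fasta"))
    readr::write_tsv(ds$truth, out("planted_truth.tsv"), progress = FALSE)
  } else {
    catalog <- if (!is.null(cfg$catalog)) read_catalog(cfg$catalog) else NULL
    seqs <- read_fasta_sequences(cfg$fasta)
    pos_set <- build_epitope_set(read_epitope_table(cfg$pos_epitopes), "positive")
    neg_set <- build_epitope_set(read_epitope_table(cfg$neg_epitopes), "negative")
    labels <- NULL
    ds <- NULL
  }

  # --- stage 1: curation --------------------------------------------------
  if (!is.null(catalog)) {
    dedup <- deduplicate_entries(catalog)
    stage_log("curation/dedupe", nrow(catalog), nrow(dedup))
    complete <- filter_complete(dedup)
    stage_log("curation/complete", nrow(dedup), nrow(complete))
    overlap <- database_overlap(dedup)
    families <- summarize_families(complete)
    write_catalog(dedup, out("catalog_deduplicated.tsv"))
    readr::write_tsv(overlap, out("database_overlap.tsv"), progress = FALSE)
    readr::write_tsv(families, out("family_summary.tsv"), progress = FALSE)
  } else {
    dedup <- complete <- overlap <- families <- NULL
  }

  # --- stage 2: identity --------------------------------------------------
  identity <- if (!is.null(complete)) family_identity_table(complete) else NULL
  if (!is.null(identity)) {
    stage_log("identity", nrow(complete), nrow(identity))
    readr::write_tsv(identity, out("family_identity.tsv"), progress = FALSE)
  }

  # --- stage 3: epitope mapping -------------------------------------------
  counts <- annotate_counts(seqs, pos_set, neg_set,
                            max_mismatches = cfg$max_mismatches)
  stage_log("mapping", length(seqs), nrow(counts))
  readr::write_tsv(counts, out("epitope_counts.tsv"), progress = FALSE)

  # --- stage 4: thresholding ----------------------------------------------
  threshold <- NULL
  if (!is.null(labels)) {
    labelled <- dplyr::inner_join(
      dplyr::transmute(counts, sequence_id = .data$sequence_id,
                       count = .data$n_positive_2m),
      labels, by = "sequence_id"
    )
    threshold <- threshold_report(labelled, threshold = cfg$threshold)
    stage_log("threshold", nrow(labelled), 1L)
    jsonlite::write_json(threshold, out("threshold_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- stage 5: phylogeny -------------------------------------------------
  tree <- NULL
  annotation <- NULL
  if (length(seqs) >= 3L && length(unique(nchar(seqs))) == 1L) {
    tree <- if (cfg$bootstrap > 0L) {
      bootstrap_support(seqs, n_replicates = cfg$bootstrap, seed = cfg$seed)
    } else {
      neighbor_joining(msa_to_distances(seqs))
    }
    annotation <- annotate_leaves(tree, counts)
    stage_log("phylogeny", length(seqs), length(tree$tip.label))
    write_newick(tree, out("tree.nwk"))
    readr::write_tsv(annotation, out("tree_annotation.tsv"), progress = FALSE)
  }

  manifest <- list(
    package = "allerpv",
    version = as.character(utils::packageVersion("allerpv")),
    seed = cfg$seed,
    parameters = list(
      max_mismatches = cfg$max_mismatches,
      threshold = cfg$threshold,
      bootstrap = cfg$bootstrap,
      synthetic = !is.null(cfg$synthetic)
    ),
    inputs = if (is.null(cfg$synthetic)) {
      list(catalog = cfg$catalog, fasta = cfg$fasta,
           pos_epitopes = cfg$pos_epitopes, neg_epitopes = cfg$neg_epitopes)
    } else {
      cfg$synthetic[setdiff(names(cfg$synthetic), "background")]
    },
    n_sequences = length(seqs),
    n_pos_epitopes = nrow(pos_set$records),
    n_neg_epitopes = nrow(neg_set$records)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(catalog = dedup, overlap = overlap, families = families,
                 identity = identity, counts = counts, threshold = threshold,
                 tree = tree, annotation = annotation, manifest = manifest,
                 dataset = ds))
}
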