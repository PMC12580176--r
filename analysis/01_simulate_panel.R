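#!/usr/bin/env Rscript
# Generate the default synthetic parvalbumin-like panel: 11 epitope-rich
# (PVB-like) and 9 epitope-poor (PVA-like) sequences of 109 residues, with
# planted positive epitopes and full ground truth. Writes the panel inputs
# every later stage consumes.

suppressPackageStartupMessages(library(allerpv))

seed <- 1L
out <- "results/01_panel"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
ds <- generate_panel(cfg)
print(ds)

check <- verify_truth(ds)
stopifnot(nrow(check$violations) == 0L)
message("ground truth verified: ", check$n_checked,
        " planted copies, 0 violations")

write_fasta_sequences(ds$sequences, file.path(out, "panel.fasta"))
readr::write_tsv(ds$labels, file.path(out, "labels.tsv"), progress = FALSE)
readr::write_tsv(ds$truth, file.path(out, "planted_truth.tsv"), progress = FALSE)
to_table <- function(set) tibble::tibble(
  peptide = set$records$peptide, polarity = set$polarity, type = "linear",
  species = "synthetic", assay_id = set$records$assay_ids)
readr::write_tsv(to_table(ds$pos_library), file.path(out, "epitopes_positive.tsv"),
                 progress = FALSE)
readr::write_tsv(to_table(ds$neg_library), file.path(out, "epitopes_negative.tsv"),
                 progress = FALSE)
write_catalog(synthetic_catalog(ds), file.path(out, "catalog.tsv"))
message("panel written under ", out)
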