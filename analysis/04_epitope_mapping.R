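#!/usr/bin/env Rscript
# Map the positive and negative linear epitope libraries onto every panel
# sequence: exact matches and matches with up to two mismatches, counted
# per distinct epitope.

suppressPackageStartupMessages(library(allerpv))

panel <- "results/01_panel"
out <- "results/04_mapping"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta_sequences(file.path(panel, "panel.fasta"))
pos <- build_epitope_set(read_epitope_table(file.path(panel, "epitopes_positive.tsv")),
                         "positive")
neg <- build_epitope_set(read_epitope_table(file.path(panel, "epitopes_negative.tsv")),
                         "negative")

counts <- annotate_counts(seqs, pos, neg, max_mismatches = 2L)
print(counts, n = nrow(counts))
message("mean #positive-2M: ",
        round(mean(counts$n_positive_2m[grepl("^allergenic", counts$sequence_id)]), 2),
        " (allergenic) vs ",
        round(mean(counts$n_positive_2m[grepl("^nonallergenic", counts$sequence_id)]), 2),
        " (less/non-allergenic)")

readr::write_tsv(counts, file.path(out, "epitope_counts.tsv"), progress = FALSE)
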