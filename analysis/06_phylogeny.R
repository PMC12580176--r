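#!/usr/bin/env Rscript
# Neighbor-joining tree over the panel (equal-length sequences treated as
# the alignment), with bootstrap supports, midpoint-rooted for display, and
# the epitope count statistics laid out in leaf order next to the tree.

suppressPackageStartupMessages(library(allerpv))

panel <- "results/01_panel"
out <- "results/06_phylogeny"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta_sequences(file.path(panel, "panel.fasta"))
tree <- bootstrap_support(seqs, n_replicates = 500L, seed = 1L)
rooted <- midpoint_root(tree)
message("tree over ", length(tree$tip.label), " leaves; supports: ",
        paste(Filter(nzchar, tree$node.label), collapse = " "))

counts <- readr::read_tsv("results/04_mapping/epitope_counts.tsv",
                          show_col_types = FALSE)
annotation <- annotate_leaves(tree, counts)
print(annotation, n = nrow(annotation))

write_newick(tree, file.path(out, "tree.nwk"))
write_newick(rooted, file.path(out, "tree_midpoint.nwk"))
readr::write_tsv(annotation, file.path(out, "tree_annotation.tsv"),
                 progress = FALSE)
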