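#!/usr/bin/env Rscript
# Curate the (synthetic) allergen catalog the way a multi-database
# compilation is curated: deduplicate entries, keep complete sequences,
# tabulate source-database overlap and per-family counts, and summarise
# per-family pairwise percent identity.

suppressPackageStartupMessages(library(allerpv))

panel <- "results/01_panel"
out <- "results/02_catalog"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

catalog <- read_catalog(file.path(panel, "catalog.tsv"))
dedup <- deduplicate_entries(catalog)
complete <- filter_complete(dedup)
message(nrow(catalog), " raw rows -> ", nrow(dedup), " unique entries -> ",
        nrow(complete), " with complete sequences")

overlap <- database_overlap(dedup)
message("entries present in all four databases: ",
        sum(overlap$n[overlap$combination ==
                        "WHO/IUIS+AllergenOnline+COMPARE+Allergome"]))
families <- summarize_families(complete)
print(families)

identity <- family_identity_table(complete)
print(identity)

write_catalog(dedup, file.path(out, "catalog_deduplicated.tsv"))
readr::write_tsv(overlap, file.path(out, "database_overlap.tsv"), progress = FALSE)
readr::write_tsv(families, file.path(out, "family_summary.tsv"), progress = FALSE)
readr::write_tsv(identity, file.path(out, "family_identity.tsv"), progress = FALSE)
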