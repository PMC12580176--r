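Package: allerpv
Title: Fish Isoallergen Curation, Epitope Mapping and Parvalbumin Allergenicity Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation and analysis toolkit for fish isoallergen and variant
    catalogs compiled from allergen databases (WHO/IUIS, AllergenOnline,
    COMPARE, Allergome). Parses WHO/IUIS isoallergen nomenclature,
    deduplicates multi-database entries, summarises database overlap and
    per-family pairwise percent identity, scores in-silico prediction
    sensitivity, maps linear B-cell epitopes onto parvalbumin sequences with
    a mismatch tolerance, optimises a family-specific allergenicity
    threshold with capture-rate and Welch-test statistics, and builds an
    annotated neighbor-joining phylogeny. Includes a synthetic-data
    generator with planted-epitope ground truth so the full pipeline runs
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    jsonlite,
    phangorn,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
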