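# allerpv

Curation and analysis toolkit for fish isoallergens and their variants,
centered on the major fish allergen parvalbumin (PV).

Fish allergenicity varies between species and even between isoforms of the
same protein: β-parvalbumins (PVB) are highly allergenic while
α-parvalbumins (PVA) are much less so, and generic *in silico*
allergenicity predictors separate them poorly. `allerpv` implements the
full analysis chain for an epitope-informed alternative:

* **Catalog curation** — WHO/IUIS-style designation parsing
  (`Gad m 1.0101` → base / isoallergen / variant), deduplication of entries
  compiled from multiple allergen databases (accession-priority UniProt >
  RefSeq > GenBank > PDB, OR-merged source flags, sequence-conflict
  errors), complete-sequence filtering, database-overlap and per-family
  summaries.
* **Identity** — pairwise global alignment (BLOSUM62, gap open 10, extend
  0.5) and per-family mean ± SD (min–max) percent-identity summaries,
  excluding self-comparisons and 100% pairs.
* **Tool sensitivity** — percent of known allergens each prediction tool
  detects, where sequences a tool cannot process (nonstandard residues
  such as `X`) count as missed.
* **Epitope mapping** — linear B-cell epitopes mapped onto sequences by
  sliding-window Hamming matching with a mismatch tolerance. Per sequence,
  four statistics: `n_positive`, `n_positive_2m` (≤ 2 mismatches),
  `n_negative`, `n_negative_2m`, counted per distinct epitope.
* **Thresholding** — family-specific classification `n_positive_2m ≥ T`
  (default `T = 4`), a balanced-accuracy threshold scan with smallest-`T`
  tie-break, capture rates, and Welch's unequal-variance t-test from group
  summaries: `t = (m1 − m2) / sqrt(s1²/n1 + s2²/n2)` with
  Welch–Satterthwaite degrees of freedom.
* **Phylogeny** — neighbor joining on Poisson-corrected distances
  (pairwise gap deletion), deterministic tie-breaks, bootstrap supports by
  column resampling, midpoint rooting, Newick I/O, and leaf-order
  annotation tables.
* **Synthetic data** — panels of epitope-rich (PVB-like) vs epitope-poor
  (PVA-like) sequences with planted epitopes and verifiable ground truth,
  so every stage runs with no download.

See the methods vignette (`vignettes/allerpv-methods.Rmd`) for the models,
parameter defaults and design decisions.

## Worked example

```r
library(allerpv)

# Welch's t-test between 11 highly allergenic PVBs and 9 less/non-allergenic
# PVs, from their #positive IEDB-2M group summaries:
w <- welch_t_test(17.1, 9.6, 11, 0.44, 0.53, 9)
#> w$t            5.745035
#> w$df           10.07447
#> w$p_two_tailed 0.0001812194

# Prediction-tool sensitivity over the 79 compiled fish allergens, from the
# shipped per-tool misclassification lists (nonstandard-residue sequences
# count as missed):
tool_sensitivities(read_tool_misclassifications(), n_total = 79)
#> # A tibble: 5 x 3
#>   tool             n_detected sensitivity
#> 1 AllerCatPro 2.0          77        97.5
#> 2 AlgPred 2.0              74        93.7
#> 3 pLM4Alg-640              71        89.9
#> 4 AllergenFP v.1.0         70        88.6
#> 5 AllerTOP v.2.0           66        83.5

# Mismatch-tolerant epitope mapping:
find_matches("ACDEF", "GGACDKFGG", max_mismatches = 2)
#> # A tibble: 1 x 2
#>   start mismatches
#> 1     3          1

# Synthetic end-to-end run (20 sequences, planted epitopes, threshold scan,
# bootstrap NJ tree), all artifacts under out_dir:
res <- run_full_analysis(run_config(synthetic = synthetic_config(seed = 1),
                                    threshold = "scan", out_dir = "run1"))
#> res$threshold$threshold          1
#> res$threshold$balanced_accuracy  1
#> res$threshold$capture$percent    100
```

The sensitivity table reads: of the 79 compiled fish isoallergens/variants
with complete sequences, each tool flagged `n_detected` as allergens;
AllerTOP's 83.5% reflects 11 misclassified entries plus the two
X-containing sequences it cannot process. In the synthetic run the scan
separates the classes perfectly (balanced accuracy 1.0) and returns the
smallest separating threshold.

The numbered drivers under `analysis/` run the same stages as a narrated
workflow (`01_simulate_panel.R` → `06_phylogeny.R`), writing tables under
`results/`.

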