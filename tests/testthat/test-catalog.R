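test_that("primary accession follows the UniProt > RefSeq > GenBank > PDB priority", {
  entry <- list(uniprot = "B5DGM7", refseq = "XP_1", genbank_protein = NA,
                pdb = NA)
  expect_equal(select_primary_accession(entry),
               list(kind = "uniprot", accession = "B5DGM7"))
  entry <- list(uniprot = NA, refseq = "XP_026771637.1",
                genbank_protein = NA, pdb = NA)
  expect_equal(select_primary_accession(entry)$accession, "XP_026771637.1")
  entry <- list(uniprot = NA, refseq = NA, genbank_protein = NA, pdb = "5ZGM_A")
  expect_equal(select_primary_accession(entry)$kind, "pdb")
  expect_error(select_primary_accession(
    list(uniprot = NA, refseq = NA, genbank_protein = NA, pdb = NA)),
    "no accession")
})

test_that("deduplication merges same-designation rows and accession-keyed rows", {
  raw <- make_raw_catalog()
  dedup <- deduplicate_entries(raw)
  # 3 Sal s 1.0101 rows collapse to 1; the two P02620 rows (no designation)
  # collapse by primary accession
  expect_equal(nrow(dedup), 4L)
  sal <- dedup[dedup$designation %in% "Sal s 1.0101", ]
  expect_equal(nrow(sal), 1L)
  expect_equal(sal$uniprot, "Q91482")
  expect_equal(sal$refseq, "NP_001117014")
  expect_equal(sal$genbank_protein, "ACI66930")
  expect_true(sal$in_whoiuis && sal$in_allergenonline && sal$in_compare &&
                sal$in_allergome)
  expect_equal(sal$pmids, "111;222")
  expect_equal(sal$completeness, "complete")
  hake <- dedup[is.na(dedup$designation), ]
  expect_equal(nrow(hake), 1L)
  expect_true(hake$in_allergenonline && hake$in_compare)
})

test_that("deduplication is idempotent and rejects sequence conflicts", {
  dedup <- deduplicate_entries(make_raw_catalog())
  expect_identical(deduplicate_entries(dedup), dedup)

  conflict <- allergen_catalog(
    designation = c("Gad m 1.0101", "Gad m 1.0101"),
    biochemical_name = "beta-parvalbumin",
    species_latin = "Gadus morhua",
    uniprot = "Q90YK9",
    sequence = c("MACAHL", "MACAHV"),
    in_whoiuis = TRUE
  )
  expect_error(deduplicate_entries(conflict), "conflicting sequences.*Gad m 1.0101")
})

test_that("complete-sequence filtering keeps order and drops the rest", {
  dedup <- deduplicate_entries(make_raw_catalog())
  complete <- filter_complete(dedup)
  expect_equal(nrow(complete), 3L)
  expect_true(all(complete$completeness == "complete"))
  expect_equal(complete$designation[!is.na(complete$designation)],
               c("Sal s 1.0101", "Gad m 1.0101"))
  all_partial <- dedup
  all_partial$completeness <- "partial"
  all_partial$sequence <- NA_character_
  expect_equal(nrow(filter_complete(all_partial)), 0L)
})

test_that("database overlap counts one cell per source combination and sums to n", {
  entries <- allergen_catalog(
    designation = c("Gad m 1.0101", "Gad m 1.0102", "Gad m 1.0201"),
    biochemical_name = "beta-parvalbumin",
    species_latin = "Gadus morhua",
    in_whoiuis = c(TRUE, TRUE, TRUE),
    in_allergenonline = c(FALSE, TRUE, TRUE),
    in_compare = c(FALSE, FALSE, TRUE),
    in_allergome = c(FALSE, FALSE, TRUE)
  )
  ov <- database_overlap(entries)
  expect_equal(nrow(ov), 3L)
  expect_true(all(ov$n == 1L))
  expect_true("WHO/IUIS+AllergenOnline+COMPARE+Allergome" %in% ov$combination)

  # property: counts always sum to the number of entries
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    flags <- matrix(runif(4 * n) < 0.5, nrow = n)
    flags[rowSums(flags) == 0, 1] <- TRUE
    entries <- allergen_catalog(
      designation = sprintf("Syn a %d.0101", seq_len(n)),
      biochemical_name = "beta-parvalbumin", species_latin = "X y",
      in_whoiuis = flags[, 1], in_allergenonline = flags[, 2],
      in_compare = flags[, 3], in_allergome = flags[, 4]
    )
    expect_equal(sum(database_overlap(entries)$n), n)
  }
})

test_that("family summary partitions entries by IUIS assignment and counts species", {
  dedup <- deduplicate_entries(make_raw_catalog())
  complete <- filter_complete(dedup)
  fam <- summarize_families(complete)
  expect_equal(sum(fam$total), nrow(complete))
  expect_equal(fam$iuis_assigned + fam$unassigned, fam$total)
  pvb <- fam[fam$biochemical_name == "beta-parvalbumin", ]
  expect_equal(pvb$total, 3L)
  expect_equal(pvb$iuis_assigned, 2L)
  expect_equal(pvb$n_species, 3L)

  single <- allergen_catalog(designation = "Gad m 1.0101",
                             biochemical_name = "beta-parvalbumin",
                             species_latin = "Gadus morhua",
                             in_whoiuis = TRUE)
  fam1 <- summarize_families(single)
  expect_equal(unlist(fam1[, c("total", "iuis_assigned", "n_species")],
                      use.names = FALSE), c(1L, 1L, 1L))
})

test_that("catalog invariants are enforced", {
  expect_error(
    allergen_catalog(designation = "Gad m 1.0101",
                     biochemical_name = "pv", species_latin = "G m",
                     sequence = "MACAHL", completeness = "absent",
                     in_whoiuis = TRUE),
    "absent"
  )
  expect_error(
    allergen_catalog(biochemical_name = "pv", species_latin = "G m",
                     in_whoiuis = TRUE),
    "designation or at least one accession"
  )
  expect_error(
    allergen_catalog(designation = "Gad m 1.0101", biochemical_name = "pv",
                     species_latin = "G m"),
    "at least one source database"
  )
})

test_that("tool sensitivity arithmetic matches missed-over-total with the nonstandard rule", {
  out <- outcomes_from_misclassification(
    misclassified = sprintf("m%02d", 1:11),
    nonstandard = c("Onc m 1.0101", "Onc m 1.0201"),
    n_total = 79
  )
  expect_equal(nrow(out), 79L)
  expect_equal(compute_sensitivity(out), 83.5)

  out <- outcomes_from_misclassification(sprintf("m%02d", 1:3),
                                         c("Onc m 1.0101", "Onc m 1.0201"), 79)
  expect_equal(compute_sensitivity(out), 93.7)

  all_det <- tibble::tibble(detected = rep(TRUE, 10),
                            rejected_nonstandard = FALSE)
  expect_equal(compute_sensitivity(all_det), 100.0)
  expect_error(compute_sensitivity(all_det[0, ]), "no outcomes")
  expect_error(compute_sensitivity(
    tibble::tibble(detected = TRUE, rejected_nonstandard = TRUE)),
    "cannot be detected")

  # monotone nonincreasing in the number of nonstandard rejections
  sens <- vapply(0:5, function(k) {
    compute_sensitivity(outcomes_from_misclassification(
      character(0), sprintf("x%d", seq_len(k)), 20))
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("nonstandard residues are anything outside the 20 canonical codes", {
  expect_equal(has_nonstandard_residues(c("ACDEFGHIKLMNPQRSTVWY", "ACXDE",
                                          "acde", "ACB")),
               c(FALSE, TRUE, FALSE, TRUE))
})
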