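test_that("epitope sets keep linear records of one polarity and deduplicate peptides", {
  raw <- tibble::tibble(
    peptide = c("ACDEFGHI", "ACDEFGHI", "KLMNPQRS", "TVWYACDE", "ACDEACDE"),
    polarity = c("positive", "positive", "positive", "positive", "negative"),
    type = c("linear", "linear", "conformational", "linear", "linear"),
    species = c("Gadus morhua", "Salmo salar", "Gadus morhua",
                "Cyprinus carpio", "Gadus morhua"),
    assay_id = c("a1", "a2", "a3", "a4", "a5")
  )
  expect_message(set <- build_epitope_set(raw, "positive"), "polarity")
  expect_equal(nrow(set$records), 2L)  # conformational dropped, duplicates merged
  merged <- set$records[set$records$peptide == "ACDEFGHI", ]
  expect_equal(merged$assay_ids, "a1;a2")
  expect_equal(merged$species, "Gadus morhua;Salmo salar")

  expect_warning(build_epitope_set(raw[raw$type == "conformational", ],
                                   "positive"), "empty")
  expect_error(build_epitope_set(
    tibble::tibble(peptide = "ACD", polarity = "positive", type = "linear"),
    "positive"), "at least 4")
})

test_that("window matching finds exact and mismatch-tolerant hits", {
  hits <- find_matches("ACDEF", "GGACDEFGG", 0)
  expect_equal(hits$start, 3L)
  expect_equal(hits$mismatches, 0L)

  expect_equal(nrow(find_matches("ACDEF", "GGACDKFGG", 0)), 0L)
  hits <- find_matches("ACDEF", "GGACDKFGG", 2)
  expect_equal(hits$start, 3L)
  expect_equal(hits$mismatches, 1L)

  # peptide longer than the sequence: no hits, no error
  expect_equal(nrow(find_matches("ACDEFGHIKL", "ACD", 2)), 0L)
  # case-insensitive
  expect_equal(find_matches("acdef", "ggAcDeFgg", 0)$start, 3L)
})

test_that("nonstandard residues never match, not even X against X", {
  expect_equal(nrow(find_matches("AXA", "AAA", 0)), 0L)
  expect_equal(nrow(find_matches("AXA", "AXA", 0)), 0L)
  # but they are tolerated as mismatches
  expect_equal(find_matches("AXA", "AAA", 1)$mismatches, 1L)
  expect_equal(find_matches("AAA", "AXA", 1)$mismatches, 1L)
})

test_that("window matching agrees with the naive double-loop oracle", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    L <- sample(4:20, 1)
    alpha <- c(CANON20, "X")
    sequence <- rand_aa(n, alpha)
    # half the time plant the peptide so hits are common
    if (runif(1) < 0.5 && L <= n) {
      st <- sample(n - L + 1, 1)
      peptide <- substr(sequence, st, st + L - 1)
    } else {
      peptide <- rand_aa(L, alpha)
    }
    m <- sample(0:3, 1)
    expect_identical(find_matches(peptide, sequence, m),
                     oracle_find_matches(peptide, sequence, m))
  }
})

test_that("counts are per distinct epitope, not per window", {
  set <- build_epitope_set(
    tibble::tibble(peptide = c("ACDEF", "KLMNP", "TVWYA"),
                   polarity = "positive", type = "linear"),
    "positive")
  seq1 <- "ACDEFKLMNPTVWYA"
  expect_equal(count_epitope_hits(set, seq1, 0), 3L)

  # one epitope present in four windows still counts once
  set1 <- build_epitope_set(
    tibble::tibble(peptide = "ACAC", polarity = "positive", type = "linear"),
    "positive")
  expect_equal(nrow(find_matches("ACAC", "ACACACACAC", 0)), 4L)
  expect_equal(count_epitope_hits(set1, "ACACACACAC", 0), 1L)
})

test_that("counts are monotone in the mismatch allowance and order-invariant", {
  set.seed(22)
  peptides <- vapply(1:8, function(i) rand_aa(sample(6:10, 1)), character(1))
  sequence <- paste0(rand_aa(40), peptides[1], rand_aa(10), peptides[3],
                     rand_aa(40))
  make_set <- function(peps) build_epitope_set(
    tibble::tibble(peptide = peps, polarity = "positive", type = "linear"),
    "positive")
  set <- make_set(peptides)
  counts <- vapply(0:4, function(m) count_epitope_hits(set, sequence, m),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  shuffled <- make_set(sample(peptides))
  for (m in 0:2) {
    expect_equal(count_epitope_hits(shuffled, sequence, m),
                 count_epitope_hits(set, sequence, m))
  }
})

test_that("reversing the sequence relocates hits predictably", {
  set.seed(23)
  n <- 60
  sequence <- rand_aa(n)
  L <- 7
  st <- 20
  peptide <- substr(sequence, st, st + L - 1)
  rev_seq <- paste(rev(strsplit(sequence, "")[[1]]), collapse = "")
  rev_pep <- paste(rev(strsplit(peptide, "")[[1]]), collapse = "")
  fwd <- find_matches(peptide, sequence, 0)
  bwd <- find_matches(rev_pep, rev_seq, 0)
  expect_setequal(bwd$start, n - L - fwd$start + 2)
})

test_that("per-sequence count rows respect the mismatch ordering invariants", {
  pos <- build_epitope_set(
    tibble::tibble(peptide = c("ACDEFGHI", "KLMNPQRS"), polarity = "positive",
                   type = "linear"), "positive")
  neg <- build_epitope_set(
    tibble::tibble(peptide = "TVWYACDE", polarity = "negative",
                   type = "linear"), "negative")

  # one exact planted epitope + one with two substitutions
  seqs <- c(
    planted = paste0("GGGG", "ACDEFGHI", "GGGG", "KLANPQRG", "GGGG"),
    empty = strrep("G", 30)
  )
  rows <- annotate_counts(seqs, pos, neg)
  planted <- rows[rows$sequence_id == "planted", ]
  expect_equal(planted$n_positive, 1L)
  expect_equal(planted$n_positive_2m, 2L)
  empty <- rows[rows$sequence_id == "empty", ]
  expect_equal(unlist(empty[, c("n_positive", "n_positive_2m", "n_negative",
                                "n_negative_2m")], use.names = FALSE),
               rep(0L, 4))
  expect_true(all(rows$n_positive <= rows$n_positive_2m))
  expect_true(all(rows$n_negative <= rows$n_negative_2m))

  expect_error(annotate_counts(c(a = "ACDE", a = "ACDE"), pos, neg),
               "duplicate")

  # pass-through annotation values are carried, not recomputed
  pt <- tibble::tibble(sequence_id = "planted", passthrough_linear80 = 91.2,
                       passthrough_3depi = 95.0)
  rows <- annotate_counts(seqs, pos, neg, passthrough = pt)
  expect_equal(rows$passthrough_linear80, c(91.2, NA))
})
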