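# Independent reference implementations used only to check package results.

CANON20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(n, alphabet = CANON20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Plain Gotoh affine-gap global alignment DP (score only); a gap of length L
# costs gap_open + L * gap_extend.
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  S <- get_blosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in b (consuming a)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in a (consuming b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - gap_extend * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - gap_extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend,
                              Iy[i, j + 1] - gap_open - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend,
                              Ix[i + 1, j] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Naive double-loop window scan; X (or any nonstandard residue) on either
# side is always a mismatch.
oracle_find_matches <- function(peptide, sequence, max_mismatches) {
  p <- strsplit(toupper(peptide), "")[[1]]
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(p)
  n <- length(s)
  starts <- integer(0)
  mms <- integer(0)
  if (L > n || L == 0L) {
    return(tibble::tibble(start = starts, mismatches = mms))
  }
  for (st in seq_len(n - L + 1L)) {
    mm <- 0L
    for (j in seq_len(L)) {
      ok <- p[j] %in% CANON20 && s[st + j - 1L] %in% CANON20 &&
        p[j] == s[st + j - 1L]
      if (!ok) mm <- mm + 1L
    }
    if (mm <= max_mismatches) {
      starts <- c(starts, st)
      mms <- c(mms, mm)
    }
  }
  tibble::tibble(start = starts, mismatches = mms)
}

# Exhaustive threshold scan maximizing balanced accuracy, smallest-T ties.
oracle_scan_threshold <- function(counts, labels) {
  pos <- counts[labels == "allergenic"]
  neg <- counts[labels == "less_non_allergenic"]
  best_t <- NA_integer_
  best_ba <- -Inf
  for (t in 0:(max(counts) + 1L)) {
    ba <- (mean(pos >= t) + mean(neg < t)) / 2
    if (ba > best_ba + 1e-12) {
      best_ba <- ba
      best_t <- t
    }
  }
  list(threshold = best_t, balanced_accuracy = best_ba)
}

# Small catalog fixture: raw (pre-deduplication) rows.
make_raw_catalog <- function() {
  allergen_catalog(
    designation = c("Sal s 1.0101", "Sal s 1.0101", "Sal s 1.0101",
                    "Gad m 1.0101", NA, NA, "Clu h 1.01"),
    biochemical_name = c(rep("beta-parvalbumin", 6), "beta-parvalbumin"),
    species_latin = c(rep("Salmo salar", 3), "Gadus morhua",
                      "Merluccius merluccius", "Merluccius merluccius",
                      "Clupea harengus"),
    uniprot = c("Q91482", NA, NA, "Q90YK9", "P02620", "P02620", NA),
    refseq = c(NA, "NP_001117014", NA, NA, NA, NA, NA),
    genbank_protein = c(NA, NA, "ACI66930", NA, NA, NA, "CAC36411"),
    sequence = c("MACAHL", "MACAHL", NA, "MAFAGIL", "MAFAGVL", "MAFAGVL",
                 NA),
    completeness = c("complete", "complete", "partial", "complete",
                     "complete", "complete", "partial"),
    in_whoiuis = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    in_allergenonline = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    in_compare = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    in_allergome = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    pmids = c("111", "222", "", "333", "", "444", "")
  )
}

# Fast synthetic config for tests.
small_synth_config <- function(seed = 1L, ...) {
  synthetic_config(n_allergenic = 6L, n_nonallergenic = 5L,
                   n_pos_epitopes = 12L, n_neg_epitopes = 8L,
                   epitope_len_range = c(8L, 12L), seed = seed, ...)
}
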