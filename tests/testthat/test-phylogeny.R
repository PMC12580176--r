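test_that("alignment distances use pairwise gap deletion", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  d <- msa_to_distances(aln, "p_distance")
  expect_equal(unname(d["a", "b"]), 0)

  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKV")
  expect_equal(unname(msa_to_distances(aln, "p_distance")["a", "b"]), 0.1)

  # Poisson correction of p = 0 is 0; of p = 0.1 is -ln(0.9)
  expect_equal(unname(msa_to_distances(aln)["a", "b"]), -log(0.9))

  # columns gapped in either sequence are skipped for that pair only
  aln <- c(a = "AC-EF", b = "ACDEF", c = "GCDEF")
  d <- msa_to_distances(aln, "p_distance")
  expect_equal(unname(d["a", "b"]), 0)      # 4 comparable columns, 0 diffs
  expect_equal(unname(d["a", "c"]), 0.25)   # 4 comparable, 1 diff
  expect_equal(unname(d["b", "c"]), 0.2)    # 5 comparable, 1 diff

  expect_error(msa_to_distances(c(a = "--", b = "AC")), "comparable")
  expect_error(msa_to_distances(c(a = "AC", b = "ACD")), "same length")
})

test_that("neighbor joining recovers additive trees exactly", {
  # ((A:1,B:2):3,(C:4,D:5)) gives these leaf-to-leaf distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 8; d["A", "D"] <- 9
  d["B", "C"] <- 9; d["B", "D"] <- 10; d["C", "D"] <- 9
  d <- d + t(d)
  tree <- neighbor_joining(d)
  expect_equal(ape::write.tree(tree), "((A:1,B:2):3,C:4,D:5);")

  # three taxa: the unique unrooted topology
  d3 <- d[1:3, 1:3]
  tree3 <- neighbor_joining(d3)
  expect_equal(sort(tree3$tip.label), c("A", "B", "C"))
  expect_equal(tree3$Nnode, 1L)

  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers random additive topologies (RF = 0)", {
  set.seed(41)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(length(true$edge.length), 0.05, 1)
    d <- ape::cophenetic.phylo(true)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    mine <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(true)), 0)
    # and agrees topologically with the reference implementation
    expect_equal(phangorn::RF.dist(ape::unroot(mine),
                                   ape::unroot(ape::nj(d))), 0)
  }
})

test_that("tie-breaking makes star-like inputs deterministic", {
  d <- matrix(1, 5, 5, dimnames = list(letters[5:1], letters[5:1]))
  diag(d) <- 0
  nwk <- replicate(5, ape::write.tree(neighbor_joining(d)))
  expect_equal(length(unique(nwk)), 1L)
  # permuting the input rows leaves the result unchanged
  perm <- sample(5)
  d2 <- d[perm, perm]
  expect_equal(ape::write.tree(neighbor_joining(d2)), nwk[[1]])
})

test_that("bootstrap supports are reproducible, bounded and high on clean splits", {
  aln <- c(a1 = "AAAAAAAAAACCCC", a2 = "AAAAAAAAAACCCC",
           b1 = "TTTTTTTTTTCCCC", b2 = "TTTTTTTTTTCCCC",
           b3 = "TTTTTTTTTTCCCA")
  t1 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  t2 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))  # the a|b split is in every replicate

  expect_error(bootstrap_support(c(a = "A", b = "C"), 10, 1), "2 columns")
})

test_that("trees round-trip through Newick with lengths and supports", {
  set.seed(42)
  base <- strsplit(rand_aa(60), "")[[1]]
  aln <- vapply(1:6, function(i) {
    mut <- base
    pos <- sample(60, 5 * i)
    mut[pos] <- sample(CANON20, length(pos), replace = TRUE)
    paste(mut, collapse = "")
  }, character(1))
  names(aln) <- sprintf("t%d", 1:6)
  tree <- bootstrap_support(aln, n_replicates = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_equal(phangorn::RF.dist(back, tree), 0)
  ord <- match(back$tip.label, tree$tip.label)
  expect_equal(sort(round(back$edge.length, 6)),
               sort(round(tree$edge.length, 6)))
  expect_setequal(back$node.label, tree$node.label)
})

test_that("leaf annotation follows tree traversal order regardless of row order", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 8; d["A", "D"] <- 9
  d["B", "C"] <- 9; d["B", "D"] <- 10; d["C", "D"] <- 9
  d <- d + t(d)
  tree <- neighbor_joining(d)
  rows <- tibble::tibble(
    sequence_id = c("C", "A", "D", "B"),
    n_positive = 1:4, n_positive_2m = 5:8,
    n_negative = 0L, n_negative_2m = 0L,
    passthrough_linear80 = NA_real_, passthrough_3depi = NA_real_
  )
  ann <- annotate_leaves(tree, rows)
  expect_equal(ann$sequence_id, c("A", "B", "C", "D"))
  shuffled <- annotate_leaves(tree, rows[sample(4), ])
  expect_equal(ann, shuffled)
  expect_equal(names(ann),
               c("sequence_id", "passthrough_linear80", "passthrough_3depi",
                 "n_positive", "n_positive_2m", "n_negative", "n_negative_2m"))
  expect_error(annotate_leaves(tree, rows[1:3, ]), "B")
})

test_that("midpoint rooting returns a rooted tree on the same leaves", {
  set.seed(43)
  true <- ape::rtree(6, rooted = FALSE)
  d <- ape::cophenetic.phylo(true)
  tree <- neighbor_joining(d[sort(rownames(d)), sort(rownames(d))])
  rooted <- midpoint_root(tree)
  expect_true(ape::is.rooted(rooted))
  expect_setequal(rooted$tip.label, tree$tip.label)
})
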