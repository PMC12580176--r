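# Distance-based phylogeny for parvalbumin panels: pairwise distances from
# a multiple alignment (p-distance or Poisson-corrected, pairwise gap
# deletion), neighbor-joining tree construction with a deterministic
# tie-break, bootstrap supports by column resampling, and leaf-order
# annotation with the per-sequence epitope statistics. Trees are standard
# ape "phylo" objects; Newick I/O goes through ape.

#' Pairwise distance matrix from a multiple alignment
#'
#' For each sequence pair, alignment columns holding a gap (`-` or `.`) in
#' either member are skipped (pairwise deletion); the p-distance is the
#' fraction of remaining columns that differ, and the Poisson-corrected
#' distance is `-ln(1 - p)` (substitutions per site under a Poisson model).
#'
#' @param aligned Named character vector of equal-length aligned sequences
#'   (>= 2), or a [Biostrings::AAStringSet].
#' @param model `"poisson_corrected"` (default) or `"p_distance"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
msa_to_distances <- function(aligned, model = c("poisson_corrected", "p_distance")) {
  model <- match.arg(model)
  if (inherits(aligned, "AAStringSet")) {
    aligned <- stats::setNames(as.character(aligned), names(aligned))
  }
  n <- length(aligned)
  if (n < 2L) stop("need at least two aligned sequences", call. = FALSE)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  if (is.null(names(aligned))) names(aligned) <- sprintf("seq%03d", seq_len(n))
  chars <- do.call(rbind, strsplit(toupper(aligned), ""))
  gap <- chars == "-" | chars == "."
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable columns between '", names(aligned)[i], "' and '",
             names(aligned)[j], "'", call. = FALSE)
      }
      p <- mean(chars[i, ok] != chars[j, ok])
      if (model == "poisson_corrected") {
        if (p >= 1) {
          stop("saturated pair '", names(aligned)[i], "' vs '",
               names(aligned)[j], "': p-distance of 1 has no finite Poisson correction",
               call. = FALSE)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration with two determinism guarantees: when several
#' pairs tie for the minimal Q criterion, the pair whose clades contain the
#' lexicographically smallest leaf labels is joined; and negative branch
#' lengths are clamped to zero with the deficit shifted to the sibling edge
#' (preserving the joined pair's distance).
#'
#' @param d Symmetric distance matrix with row/column names (>= 3 taxa).
#' @return An unrooted `phylo` object (ape) with branch lengths.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must have row names", call. = FALSE)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix must be finite", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-9) || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  nwk <- labs            # growing newick fragment per active node
  minleaf <- labs        # smallest leaf label below each active node
  D <- d
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  join_nwk <- function(a, la, b, lb) {
    # child with the smaller minimal leaf first, for byte-stable output
    sprintf("(%s:%.10g,%s:%.10g)", a, la, b, lb)
  }
  while (length(nwk) > 3L) {
    r <- length(nwk)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      leaves <- sort(c(minleaf[ij[1]], minleaf[ij[2]]))
      paste(leaves, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    lens <- clamp_pair(li, lj)
    first <- if (minleaf[i] <= minleaf[j]) c(i, j) else c(j, i)
    lens_ord <- if (first[1] == i) lens else rev(lens)
    new_nwk <- join_nwk(nwk[first[1]], lens_ord[1], nwk[first[2]], lens_ord[2])
    new_min <- min(minleaf[i], minleaf[j])
    others <- setdiff(seq_len(r), c(i, j))
    new_d <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], new_d),
               c(new_d, 0))
    nwk <- c(nwk[others], new_nwk)
    minleaf <- c(minleaf[others], new_min)
  }
  # final three-way join at an (unrooted) trifurcating root
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  ord <- order(minleaf)
  parts <- sprintf("%s:%.10g", nwk, c(la, lb, lc))[ord]
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  tree
}

# Canonical label-set strings for the non-trivial bipartitions of a tree;
# each split is represented by the side NOT containing the alphabetically
# first tip, so splits compare across trees regardless of rooting.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  parts <- ape::prop.part(tree)
  out <- vapply(parts, function(idx) {
    side <- tips[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  out
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times; the support of each internal edge is
#' the percentage of replicate trees containing the same leaf bipartition.
#' Supports are stored as node labels (ape convention), rounded to whole
#' percent; the root node is left unlabelled.
#'
#' @inheritParams msa_to_distances
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the supports exactly.
#' @return A `phylo` object with `node.label` supports.
#' @export
bootstrap_support <- function(aligned, n_replicates = 500L, seed = 1L,
                              model = "poisson_corrected") {
  stopifnot(n_replicates >= 1L)
  if (inherits(aligned, "AAStringSet")) {
    aligned <- stats::setNames(as.character(aligned), names(aligned))
  }
  n_col <- unique(nchar(aligned))
  if (length(n_col) != 1L || n_col < 2L) {
    stop("alignment must have >= 2 columns of equal length", call. = FALSE)
  }
  full <- neighbor_joining(msa_to_distances(aligned, model))
  chars <- do.call(rbind, strsplit(toupper(aligned), ""))
  split_counts <- new.env(parent = emptyenv())
  n_ok <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(n_col, n_col, replace = TRUE)
      rep_aln <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(rep_aln) <- names(aligned)
      # a resample can saturate a pair (p-distance 1); such replicates carry
      # no tree and are excluded from the support denominator
      rep_tree <- try(neighbor_joining(msa_to_distances(rep_aln, model)),
                      silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      n_ok <- n_ok + 1L
      for (s in unique(stats::na.omit(tree_bipartitions(rep_tree)))) {
        split_counts[[s]] <- (if (is.null(split_counts[[s]])) 0L else split_counts[[s]]) + 1L
      }
    }
  })
  if (n_ok == 0L) stop("no bootstrap replicate produced a tree", call. = FALSE)
  splits <- tree_bipartitions(full)
  support <- vapply(splits, function(s) {
    if (is.na(s)) return(NA_real_)
    cnt <- split_counts[[s]]
    100 * (if (is.null(cnt)) 0L else cnt) / n_ok
  }, numeric(1))
  full$node.label <- ifelse(is.na(support), "", as.character(round(support)))
  full
}

#' Midpoint-root a tree for display
#'
#' @param tree A `phylo` object.
#' @return The midpoint-rooted tree.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Leaf-order annotation table for a tree
#'
#' Orders the per-sequence epitope statistics by the tree's leaf traversal
#' order (the top-to-bottom order the tips would be drawn in), so the table
#' can be laid out next to the tree.
#'
#' @param tree A `phylo` object whose tip labels are sequence ids.
#' @param rows An [annotate_counts()] tibble covering every leaf.
#' @return `rows` reordered to leaf order, columns `sequence_id`,
#'   `passthrough_linear80`, `passthrough_3depi`, `n_positive`,
#'   `n_positive_2m`, `n_negative`, `n_negative_2m`.
#' @export
annotate_leaves <- function(tree, rows) {
  tree <- stats::reorder(tree, "cladewise")
  tip_order <- tree$edge[, 2][tree$edge[, 2] <= length(tree$tip.label)]
  leaves <- tree$tip.label[tip_order]
  missing <- setdiff(leaves, rows$sequence_id)
  if (length(missing) > 0L) {
    stop("no annotation row for leaf/leaves: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- rows[match(leaves, rows$sequence_id), , drop = FALSE]
  out[, c("sequence_id", "passthrough_linear80", "passthrough_3depi",
          "n_positive", "n_positive_2m", "n_negative", "n_negative_2m")]
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file (internal node labels are read as
#'   bootstrap supports).
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object (node labels, if any, are written as
#'   internal node labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
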