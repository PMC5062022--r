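# Distance-based phylogenetics for clone-library OTU proteins: p-distances
# with pairwise deletion, a neighbor-joining implementation with
# deterministic tie-breaking and negative-branch clamping, and bootstrap
# support by column resampling. Trees are ape "phylo" objects, so the whole
# ape toolbox (plotting, newick I/O, comparison) applies downstream.

#' Pairwise p-distance between aligned sequences
#'
#' Fraction of differing sites over compared sites, excluding columns where
#' either sequence has a gap (pairwise deletion).
#'
#' @param seq_a,seq_b Aligned sequence strings of equal length.
#' @return Proportion of differing sites.
#' @export
p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stopf("sequences have different aligned lengths")
  a <- seq_to_chars(toupper(seq_a)); b <- seq_to_chars(toupper(seq_b))
  ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  if (!any(ok)) stopf("no comparable (gap-free) sites")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise distance matrix of an alignment
#'
#' @param alignment Named character vector of aligned sequences.
#' @param model `"p"` (default) for the raw p-distance, `"poisson"` for the
#'   Poisson correction `-ln(1 - p)`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
dist_matrix <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  n <- length(alignment)
  labels <- names(alignment) %||% paste0("t", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- p_distance(alignment[[i]], alignment[[j]])
    if (model == "poisson") {
      if (p >= 1) stopf("Poisson correction undefined at p = 1")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimising
#' `Q(i, j) = (m - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with branch
#' lengths from the standard split formula and the reduced matrix
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. Exact Q ties are broken by
#' the lowest index pair, so output is deterministic. Negative branch lengths
#' are clamped to 0 with the deficit transferred to the sister edge, which
#' preserves the path length through the join. The result is the standard
#' unrooted NJ tree with a basal trifurcation; NJ is consistent, so additive
#' matrices are recovered exactly.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with labelled rows.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stopf("need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8) || any(d < 0) ||
      any(abs(diag(d)) > 1e-12))
    stopf("distance matrix must be symmetric, non-negative, zero-diagonal")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # active node labels are newick fragments; joining wraps two fragments
  frag <- as.list(labels)
  D <- unname(d)
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  while (length(frag) > 3) {
    m <- length(frag)
    r <- rowSums(D)
    qmin <- Inf; bi <- 1L; bj <- 2L
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      if (q < qmin) { qmin <- q; bi <- i; bj <- j }
    }
    li <- D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- D[bi, bj] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[[bi]], fmt(li),
                       frag[[bj]], fmt(lj))
    keep <- setdiff(seq_len(m), c(bi, bj))
    dnew <- (D[bi, keep] + D[bj, keep] - D[bi, bj]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    frag <- c(frag[keep], newfrag)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[[1]], fmt(la),
                 frag[[2]], fmt(lb), frag[[3]], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa in two; splits are canonicalised to the
#' side not containing the first tip label and keyed by the sorted labels,
#' so trees can be compared regardless of rotation or root placement.
#'
#' @param tree A `phylo` tree.
#' @return Character vector of split keys (one per internal edge).
#' @export
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  n <- length(labels)
  ref <- min(labels)
  keys <- vapply(parts, function(side) {
    side <- labels[side]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and reports, for every non-trivial bipartition of the
#' original tree, the percentage of replicate trees containing it. Seeded
#' and reproducible.
#'
#' @param alignment Named character vector of >= 4 aligned sequences.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param model Distance model, see [dist_matrix()].
#' @return List with `tree` (the original NJ tree, `node.label` set to the
#'   supports) and `support` (named numeric vector, percent, keyed by split).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = NULL,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  if (length(alignment) < 4) stopf("need >= 4 sequences")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  len <- unique(nchar(alignment))
  if (length(len) != 1) stopf("sequences are not aligned (unequal lengths)")
  chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(chars) <- names(alignment)
  tree0 <- neighbor_joining(dist_matrix(alignment, model))
  splits0 <- tree_bipartitions(tree0)
  count <- setNames(numeric(length(splits0)), splits0)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(len, len, replace = TRUE)
      boot <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                             collapse = ""), rownames(chars))
      bs <- tree_bipartitions(neighbor_joining(dist_matrix(boot, model)))
      hit <- splits0 %in% bs
      count[hit] <- count[hit] + 1
    }
  })
  support <- 100 * count / n_replicates
  tree0$node.label <- c("", vapply(splits_by_node(tree0), function(k) {
    if (is.na(k)) "" else fmt_support(support[[k]])
  }, ""))[seq_len(tree0$Nnode)]
  list(tree = tree0, support = support)
}

fmt_support <- function(x) format(round(x, 1), trim = TRUE)

# split key per internal node (excluding the root, which has none)
splits_by_node <- function(tree) {
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  n <- length(labels)
  ref <- min(labels)
  vapply(parts[-1], function(side) {
    side <- labels[side]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
}

#' Write a tree to newick
#'
#' Standard newick with branch lengths; any `node.label` (e.g. bootstrap
#' supports) appears as internal labels. Reading the string back yields the
#' same bipartitions and branch lengths.
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; if omitted, the newick string is returned.
#' @return The newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  nwk <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
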