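# Tree-space congruence: bipartition comparison, quartet distances,
# Cailliez correction and low-dimensional embeddings of tree samples.

#' Read trees from Newick or NEXUS
#'
#' Dispatches on content: files beginning with `#NEXUS` go through
#' [ape::read.nexus()], anything else through [ape::read.tree()].
#' Support values stored as node labels are tolerated and ignored by
#' the topological analyses.
#'
#' @param path tree file.
#' @return a `phylo` or `multiPhylo` object.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
  else ape::read.tree(path)
}

#' Prune trees to their common leaf set
#'
#' Restricts every tree to the taxa shared by all trees.  Degree-2
#' nodes created by pruning are suppressed and branch lengths along
#' suppressed paths are summed (via [ape::keep.tip()]).
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`).
#' @return list of pruned `phylo` objects, same order.
#' @export
prune_to_common <- function(trees) {
  trees <- as_tree_list(trees)
  if (length(trees) < 2L) stop("need at least two trees")
  common <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (length(common) < 2L)
    stop("trees share fewer than two taxa (intersection is empty or trivial)")
  lapply(trees, ape::keep.tip, tip = common)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  stopifnot(is.list(trees), all(vapply(trees, inherits, logical(1), "phylo")))
  trees
}

# Canonical keys for the non-trivial splits (unrooted mode) or clades
# (rooted mode) of a tree.  Unrooted splits are represented by the side
# not containing the alphabetically first taxon.
tree_splits <- function(tree, mode = c("unrooted", "rooted")) {
  mode <- match.arg(mode)
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (clade in pp) {
    side <- labs[clade]
    if (mode == "unrooted" && anchor %in% side)
      side <- setdiff(tips, side)
    sz <- length(side)
    if (mode == "unrooted") {
      if (sz < 2L || sz > length(tips) - 2L) next
    } else {
      if (sz < 2L || sz >= length(tips)) next
    }
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Topological congruence between two trees
#'
#' Compares the sets of non-trivial leaf bipartitions (unrooted mode,
#' default) or clades (rooted mode) of two trees on the same leaf set.
#' Because "congruent node positions" is directional when the trees
#' differ in resolution, counts are reported in both directions.
#'
#' @param treeA,treeB `phylo` objects with identical leaf sets (prune
#'   first, see [prune_to_common()]).
#' @param mode `"unrooted"` (bipartitions) or `"rooted"` (clades).
#' @return object of class `"tree_congruence"`: list with
#'   `shared_nodes`, `incongruent_nodes_ab` (splits of A absent from
#'   B), `incongruent_nodes_ba`, `fraction_congruent_ab`
#'   (= shared / splits of A), `fraction_congruent_ba`, `n_splits_a`,
#'   `n_splits_b`.
#' @export
congruence <- function(treeA, treeB, mode = c("unrooted", "rooted")) {
  mode <- match.arg(mode)
  check_same_leaves(treeA, treeB)
  sa <- tree_splits(treeA, mode)
  sb <- tree_splits(treeB, mode)
  shared <- length(intersect(sa, sb))
  structure(
    list(shared_nodes = shared,
         incongruent_nodes_ab = length(setdiff(sa, sb)),
         incongruent_nodes_ba = length(setdiff(sb, sa)),
         fraction_congruent_ab = if (length(sa)) shared / length(sa) else NA,
         fraction_congruent_ba = if (length(sb)) shared / length(sb) else NA,
         n_splits_a = length(sa), n_splits_b = length(sb), mode = mode),
    class = "tree_congruence")
}

#' @export
print.tree_congruence <- function(x, ...) {
  cat(sprintf("<tree_congruence> (%s) shared %d | A-only %d | B-only %d\n",
              x$mode, x$shared_nodes, x$incongruent_nodes_ab,
              x$incongruent_nodes_ba))
  cat(sprintf("  congruent fraction: A %.3f (of %d), B %.3f (of %d)\n",
              x$fraction_congruent_ab, x$n_splits_a,
              x$fraction_congruent_ba, x$n_splits_b))
  invisible(x)
}

check_same_leaves <- function(treeA, treeB) {
  if (!setequal(treeA$tip.label, treeB$tip.label))
    stop("trees have different leaf sets; prune to a common set first")
  invisible(TRUE)
}

# Induced quartet states of a tree, one entry per 4-leaf subset of the
# sorted leaf set (combn order).  States: 1 = ab|cd, 2 = ac|bd,
# 3 = ad|bc, 0 = unresolved.  Uses the four-point condition on
# topological (unit-branch-length) path distances.
quartet_states <- function(tree, quartets = NULL) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  if (n < 4L) stop("need at least 4 leaves for quartet analysis")
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- ape::cophenetic.phylo(tr)[tips, tips]
  if (is.null(quartets)) quartets <- utils::combn(n, 4L)
  a <- quartets[1L, ]; b <- quartets[2L, ]
  c_ <- quartets[3L, ]; d <- quartets[4L, ]
  s1 <- D[cbind(a, b)] + D[cbind(c_, d)]
  s2 <- D[cbind(a, c_)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, c_)]
  S <- cbind(s1, s2, s3)
  mn <- pmin(s1, s2, s3)
  nmin <- (s1 == mn) + (s2 == mn) + (s3 == mn)
  state <- integer(length(mn))
  resolved <- nmin == 1L
  state[resolved] <- max.col(-S[resolved, , drop = FALSE])
  state
}

#' Quartet distance between two unrooted trees
#'
#' Counts the 4-leaf subsets whose induced subtree topologies differ
#' between the two trees.  Each quartet is in one of three resolved
#' states or unresolved (a polytomy in the induced subtree);
#' `unresolved_policy` controls whether a resolved state counts as
#' different from an unresolved one (`"differ"`, default) or such pairs
#' are skipped (`"ignore"`).
#'
#' @param treeA,treeB `phylo` objects on the same leaf set (n >= 4).
#' @param unresolved_policy `"differ"` or `"ignore"`.
#' @return non-negative integer; at most `choose(n, 4)`.
#' @export
quartet_distance <- function(treeA, treeB,
                             unresolved_policy = c("differ", "ignore")) {
  unresolved_policy <- match.arg(unresolved_policy)
  check_same_leaves(treeA, treeB)
  if (length(treeA$tip.label) < 4L) stop("need at least 4 leaves")
  sa <- quartet_states(treeA)
  sb <- quartet_states(treeB)
  count_quartet_diffs(sa, sb, unresolved_policy)
}

count_quartet_diffs <- function(sa, sb, unresolved_policy) {
  if (unresolved_policy == "differ") sum(sa != sb)
  else sum(sa != sb & sa != 0L & sb != 0L)
}

#' Symmetric dissimilarity matrix container
#'
#' @param values symmetric numeric matrix, zero diagonal, non-negative.
#' @param labels optional labels (default: rownames or indices).
#' @param is_euclidean `"yes"`, `"no"` or `"unknown"`.
#' @return object of class `"dist_matrix"`.
#' @export
dist_matrix <- function(values, labels = NULL,
                        is_euclidean = c("unknown", "yes", "no")) {
  is_euclidean <- match.arg(is_euclidean)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (any(values < 0)) stop("negative dissimilarities not allowed")
  if (any(abs(values - t(values)) > 0)) stop("matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  if (is.null(labels))
    labels <- rownames(values) %||% as.character(seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values,
                 is_euclidean = is_euclidean),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d x %d (Euclidean: %s)\n",
              nrow(x$values), ncol(x$values), x$is_euclidean))
  invisible(x)
}

#' Pairwise quartet-distance matrix over a tree sample
#'
#' Computes induced quartet states once per tree, then counts
#' differing quartets for every tree pair.  Topological duplicates
#' (identical quartet-state vectors) are detected and counted, for
#' density shading of tree-space plots.
#'
#' @param trees list of `phylo` objects on a common leaf set.
#' @param unresolved_policy see [quartet_distance()].
#' @return a [dist_matrix()] with attribute `"duplicates"`: integer
#'   vector giving, for each tree, the number of trees in the sample
#'   (including itself) sharing its topology.
#' @export
pairwise_quartet_matrix <- function(trees,
                                    unresolved_policy = c("differ", "ignore")) {
  unresolved_policy <- match.arg(unresolved_policy)
  trees <- as_tree_list(trees)
  if (length(trees) < 2L) stop("need at least two trees")
  for (i in seq_along(trees)[-1L]) check_same_leaves(trees[[1L]], trees[[i]])
  states <- lapply(trees, quartet_states)
  t <- length(trees)
  M <- matrix(0, t, t)
  for (i in seq_len(t - 1L)) {
    for (j in (i + 1L):t) {
      M[i, j] <- M[j, i] <-
        count_quartet_diffs(states[[i]], states[[j]], unresolved_policy)
    }
  }
  labels <- names(trees) %||% paste0("tree", seq_len(t))
  keys <- vapply(states, paste, character(1), collapse = ",")
  dup <- as.integer(table(keys)[keys])
  out <- dist_matrix(M, labels = labels)
  attr(out, "duplicates") <- dup
  out
}

#' Mean distance from a group of trees to a reference
#'
#' @param D a [dist_matrix()].
#' @param group indices or labels of the group.
#' @param ref index or label of the reference tree.
#' @return mean of the group-to-reference distances.
#' @export
mean_distance_to_reference <- function(D, group, ref) {
  stopifnot(inherits(D, "dist_matrix"))
  mean(D$values[group, ref])
}

# Gower-centered -1/2 D^2 matrix
gower_center <- function(D, power = 2) {
  n <- nrow(D)
  C <- diag(n) - matrix(1 / n, n, n)
  -0.5 * C %*% (D^power) %*% C
}

is_euclidean_matrix <- function(D, tol = 1e-8) {
  ev <- eigen(gower_center(D), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  min(ev) >= -tol * scale
}

#' Cailliez additive correction
#'
#' Finds the smallest constant `c >= 0` such that adding `c` to every
#' off-diagonal dissimilarity yields a Euclidean-embeddable matrix.
#' The constant is the largest eigenvalue of the standard 2n x 2n
#' companion matrix built from the Gower-centered first and second
#' powers of the dissimilarities; an already-Euclidean input returns
#' `c = 0` unchanged.
#'
#' @param D a [dist_matrix()] or a symmetric matrix.
#' @param tol relative tolerance for the Euclidean spectrum check.
#' @return list with `D` (corrected [dist_matrix()], flagged
#'   `is_euclidean = "yes"`) and `c` (the additive constant).
#' @export
cailliez <- function(D, tol = 1e-8) {
  if (!inherits(D, "dist_matrix")) D <- dist_matrix(D)
  V <- D$values
  n <- nrow(V)
  if (n < 2L) stop("need at least two points")
  if (is_euclidean_matrix(V, tol)) {
    out <- dist_matrix(V, labels = D$labels, is_euclidean = "yes")
    return(list(D = out, c = 0))
  }
  d1 <- gower_center(V, power = 1)
  d2 <- gower_center(V, power = 2)
  comp <- rbind(cbind(matrix(0, n, n), 2 * d2),
                cbind(-diag(n), -4 * d1))
  ev <- eigen(comp, only.values = TRUE)$values
  c_const <- max(Re(ev))
  if (c_const < 0) c_const <- 0
  Vc <- V + c_const
  diag(Vc) <- 0
  out <- dist_matrix(Vc, labels = D$labels, is_euclidean = "yes")
  list(D = out, c = c_const)
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and
#' returns the top-k principal coordinate axes with the fraction of
#' (positive-eigenvalue) variance each explains.
#'
#' @param D a [dist_matrix()] (apply [cailliez()] first if the matrix
#'   is not Euclidean) or symmetric matrix.
#' @param k number of output dimensions.
#' @return object of class `"tree_embedding"`: list with `coordinates`
#'   (points x k, rownames = labels), `method = "cmds"`, `eigenvalues`,
#'   `variance_explained`, `stress = NA`.
#' @export
classical_mds <- function(D, k = 2) {
  if (!inherits(D, "dist_matrix")) D <- dist_matrix(D)
  if (identical(D$is_euclidean, "no"))
    warning("matrix flagged non-Euclidean; consider cailliez() first")
  n <- nrow(D$values)
  if (k >= n) stop("k must be smaller than the number of points")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D$values), k = n - 1L, eig = TRUE))
  pos <- fit$eig[fit$eig > max(fit$eig) * 1e-12]
  if (k > length(pos))
    stop(sprintf("k = %d exceeds the %d positive eigenvalues", k,
                 length(pos)))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- D$labels
  structure(
    list(coordinates = coords, method = "cmds", eigenvalues = fit$eig,
         variance_explained = pos / sum(pos), stress = NA_real_),
    class = "tree_embedding")
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Rank-based stress minimization (via [vegan::monoMDS()]) from a
#' metric-scaling start plus seeded random restarts; the lowest-stress
#' configuration wins.  Stress is reported on the 0--1 scale; there is
#' no per-axis variance decomposition in NMDS.
#'
#' @param D a [dist_matrix()] or symmetric matrix.
#' @param k output dimensions.
#' @param seed master seed for the random restarts.
#' @param restarts number of random starts in addition to the metric
#'   start (default 20).
#' @param maxit maximum iterations per start (default 500).
#' @param stress_tol stress convergence tolerance (default 1e-6).
#' @return a `"tree_embedding"` with `method = "nmds"`, `stress`, and
#'   `converged` flag; non-convergence of the best start produces a
#'   warning, not an error.
#' @export
nmds_embed <- function(D, k = 2, seed = 1, restarts = 20, maxit = 500,
                       stress_tol = 1e-6) {
  if (!inherits(D, "dist_matrix")) D <- dist_matrix(D)
  d <- stats::as.dist(D$values)
  n <- nrow(D$values)
  best <- NULL
  for (i in 0:restarts) {
    if (i == 0L) {
      init <- suppressWarnings(stats::cmdscale(d, k = k))
      if (ncol(init) < k)
        init <- cbind(init, matrix(0, n, k - ncol(init)))
    } else {
      set.seed(derive_seed(seed, i))
      init <- matrix(stats::runif(n * k, -1, 1), n, k)
    }
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = maxit, smin = stress_tol,
                          sfgrmin = 1e-7)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  converged <- best$icause %in% c(1L, 2L, 3L)
  if (!converged)
    warning("NMDS did not meet its convergence criteria; returning the best configuration found")
  coords <- best$points
  rownames(coords) <- D$labels
  structure(
    list(coordinates = coords, method = "nmds",
         eigenvalues = NULL, variance_explained = NULL,
         stress = best$stress, converged = converged),
    class = "tree_embedding")
}

#' @export
print.tree_embedding <- function(x, ...) {
  cat(sprintf("<tree_embedding> %s, %d points x %d dims",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  if (x$method == "cmds") {
    ve <- x$variance_explained[seq_len(min(2, length(x$variance_explained)))]
    cat(sprintf("; variance explained: %s",
                paste(sprintf("%.1f%%", 100 * ve), collapse = ", ")))
  } else {
    cat(sprintf("; stress = %.4f", x$stress))
  }
  cat("\n")
  invisible(x)
}

#' Plot a tree-space embedding
#'
#' Scatter of the first two embedding axes.  Point shading darkens with
#' the number of topological duplicates at that location and plotting
#' symbols distinguish groups.
#'
#' @param x a `"tree_embedding"`.
#' @param groups optional factor assigning trees to samples.
#' @param duplicates optional integer vector of per-tree duplicate
#'   counts (see [pairwise_quartet_matrix()]).
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tree_embedding <- function(x, groups = NULL, duplicates = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < 2L) co <- cbind(co, 0)
  shade <- if (is.null(duplicates)) rep(0.2, nrow(co))
           else 0.8 * (duplicates / max(duplicates))
  col <- grDevices::grey(0.8 - 0.75 * shade)
  pch <- if (is.null(groups)) 19L else as.integer(factor(groups)) + 14L
  xlab <- if (x$method == "cmds")
    sprintf("axis 1 (%.1f%%)", 100 * x$variance_explained[1])
  else "NMDS axis 1"
  ylab <- if (x$method == "cmds")
    sprintf("axis 2 (%.1f%%)", 100 * x$variance_explained[2])
  else "NMDS axis 2"
  graphics::plot(co[, 1], co[, 2], col = col, pch = pch, xlab = xlab,
                 ylab = ylab, ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     pch = sort(unique(pch)), bty = "n")
  invisible(x)
}
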