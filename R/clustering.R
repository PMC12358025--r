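#' UPGMA hierarchical clustering of a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the pair of
#' clusters at minimum distance, replacing their distances to every other
#' cluster by the size-weighted arithmetic average. Node heights are half the
#' merge distance, so the tree is ultrametric with leaves at height 0. Ties
#' are broken deterministically by merging the pair whose cluster labels
#' (the lexicographically smallest leaf label in each cluster) sort first.
#'
#' @param d symmetric numeric matrix (or `dist`) with zero diagonal and row
#'   names; `NA`/`NaN` entries are an error.
#' @return An object of class `upgma_tree`: `merge` and `height` in
#'   [stats::hclust()] convention (heights are half merge distances),
#'   `labels`, and `merge_dist` (the raw merge distances).
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("NA/NaN in distance matrix")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("T", seq_len(n))
  # active clusters: id (negative = leaf index, positive = merge row),
  # size, representative label for tie-breaking
  id <- -seq_len(n); size <- rep(1L, n); rep_lab <- labs
  D <- d; diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    dmin <- min(D)
    cand <- which(D == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on the sorted pair of representative labels
    key <- apply(cand, 1L, function(ij) {
      pl <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(pl, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- min(pick); j <- max(pick)
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dmin / 2
    ni <- size[i]; nj <- size[j]
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- D[, i] <- newd
    D[i, i] <- Inf
    keep <- setdiff(seq_len(ncol(D)), j)
    D <- D[keep, keep, drop = FALSE]
    id[i] <- step; size[i] <- ni + nj
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    id <- id[keep]; size <- size[keep]; rep_lab <- rep_lab[keep]
  }
  structure(list(merge = merge, height = height, labels = labs,
                 merge_dist = 2 * height),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree with", length(x$labels), "leaves; root height",
      format(max(x$height)), "\n")
  invisible(x)
}

#' Convert a UPGMA tree to an hclust object
#'
#' Heights follow the `hclust` convention (the merge distance, i.e. twice
#' the ultrametric node height), so `stats::cutree()` and plotting work as
#' usual.
#'
#' @param x an `upgma_tree`.
#' @param ... unused.
#' @return A [stats::hclust] object.
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) ord <<- c(ord, -node)
    else { walk(x$merge[node, 1L]); walk(x$merge[node, 2L]) }
  }
  walk(nrow(x$merge))
  structure(list(merge = x$merge, height = x$merge_dist, order = ord,
                 labels = x$labels, method = "upgma",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Serialize an ultrametric tree to Newick
#'
#' Branch lengths are parent height minus child height (leaves at height 0).
#'
#' @param t an `upgma_tree`, or a single label for a one-leaf tree.
#' @param digits significant digits for branch lengths.
#' @return Newick string terminated by `";"`.
#' @export
to_newick <- function(t, digits = 10) {
  if (is.character(t) && length(t) == 1L) return(paste0(t, ";"))
  stopifnot(inherits(t, "upgma_tree"))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  # children ordered by their smallest leaf label, so equal trees serialize
  # identically whatever the input row order was
  node_str <- function(node, parent_h) {
    if (node < 0L)
      return(list(str = paste0(t$labels[-node], ":", fmt(parent_h)),
                  minlab = t$labels[-node]))
    h <- t$height[node]
    c1 <- node_str(t$merge[node, 1L], h)
    c2 <- node_str(t$merge[node, 2L], h)
    if (c2$minlab < c1$minlab) { tmp <- c1; c1 <- c2; c2 <- tmp }
    list(str = paste0("(", c1$str, ",", c2$str, "):", fmt(parent_h - h)),
         minlab = c1$minlab)
  }
  root <- nrow(t$merge)
  h <- t$height[root]
  c1 <- node_str(t$merge[root, 1L], h)
  c2 <- node_str(t$merge[root, 2L], h)
  if (c2$minlab < c1$minlab) { tmp <- c1; c1 <- c2; c2 <- tmp }
  paste0("(", c1$str, ",", c2$str, ");")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-D^2/2` and
#' eigendecomposition, with axes scaled by the square root of their
#' eigenvalues. Axes with non-positive eigenvalues are dropped (negative
#' eigenvalues — possible for non-Euclidean distances such as band-sharing
#' GD — are still reported), and explained variance is taken over the sum of
#' positive eigenvalues.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param n_axes number of axes to return (default 2; truncated with a
#'   warning if fewer positive eigenvalues exist).
#' @return An object of class `ordination`: `coordinates` (items x axes),
#'   `eigenvalues` (all, descending), `variance_explained` (per returned
#'   axis), `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(d)
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  ev <- sort(mds$eig, decreasing = TRUE)
  npos <- sum(ev > max(ev[1], 0) * 1e-12)
  if (n_axes > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning that many axes")
    n_axes <- npos
  }
  coords <- if (n_axes > 0L) mds$points[, seq_len(n_axes), drop = FALSE]
            else matrix(0, n, 0L)
  if (n_axes > 0L)
    colnames(coords) <- paste0("Axis", seq_len(n_axes))
  rownames(coords) <- rownames(d)
  pos_sum <- sum(ev[ev > 0])
  ve <- if (n_axes > 0L && pos_sum > 0) ev[seq_len(n_axes)] / pos_sum
        else numeric(0)
  structure(list(coordinates = coords, eigenvalues = ev,
                 variance_explained = ve,
                 negative_eigenvalues = ev[ev < 0]),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", nrow(x$coordinates), "items,",
      ncol(x$coordinates), "axes;",
      if (length(x$variance_explained))
        paste0("variance explained ",
               paste(sprintf("%.1f%%", 100 * x$variance_explained),
                     collapse = ", "))
      else "", "\n")
  invisible(x)
}

#' Column-standardize a trait table
#'
#' Subtracts the column mean and divides by the sample standard deviation
#' (n - 1). A zero-variance trait is an error (it carries no information and
#' breaks the scaling).
#'
#' @param x numeric matrix, traits in columns.
#' @return Matrix of the same shape with columns at mean 0, sd 1.
#' @export
standardize_traits <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("trait table contains missing values")
  sds <- apply(x, 2L, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance trait(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of a standardized trait matrix
#'
#' Eigendecomposition of the correlation structure of pre-standardized data
#' (no further centring or scaling is applied), reporting the fraction of
#' total variance explained per axis.
#'
#' @param x standardized numeric matrix (samples x traits).
#' @param n_axes number of axes to return (default 2).
#' @return An `ordination` object; `eigenvalues` are the PC variances and
#'   `variance_explained` sums to 1 over all axes.
#' @export
trait_pca <- function(x, n_axes = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  n_axes <- min(n_axes, length(ev))
  coords <- pr$x[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  structure(list(coordinates = coords, eigenvalues = ev,
                 variance_explained = ev[seq_len(n_axes)] / sum(ev),
                 negative_eigenvalues = numeric(0),
                 rotation = pr$rotation),
            class = "ordination")
}
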