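#' Classify seed length into large and small seed types
#'
#' The cut is at 9.0 mm: large seed-type at >= 9.0 mm, small below.
#'
#' @param length_mm numeric vector of seed lengths in mm (all positive).
#' @return Factor with levels `large`, `small`.
#' @export
classify_seed <- function(length_mm) {
  if (anyNA(length_mm) || any(length_mm <= 0))
    stop("seed lengths must be positive and non-missing")
  factor(ifelse(length_mm >= 9.0, "large", "small"),
         levels = c("large", "small"))
}

#' Region-by-seed-class contingency table
#'
#' Counts accessions per region/group and seed class; the result feeds
#' [chisq_independence()].
#'
#' @param meta metadata `data.frame` with `region_group` and
#'   `seed_length_mm` (rows with missing seed length are dropped and
#'   reported via an attribute).
#' @param grouping optional alternative group labels (defaults to
#'   `meta$region_group`).
#' @return Integer matrix, regions x `c("large", "small")`, with attribute
#'   `dropped` listing IDs without seed length.
#' @export
seed_class_table <- function(meta, grouping = NULL) {
  if (is.null(grouping)) grouping <- meta$region_group
  keep <- !is.na(meta$seed_length_mm)
  dropped <- if ("id" %in% names(meta)) meta$id[!keep] else which(!keep)
  cls <- classify_seed(meta$seed_length_mm[keep])
  tab <- table(grouping[keep], cls)
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  attr(out, "dropped") <- dropped
  out
}

#' Morphological clustering of a trait table
#'
#' Standardizes the traits, computes Euclidean distances, builds a UPGMA
#' tree and cuts it into `n_clusters` groups (at the lowest height giving
#' exactly that many components).
#'
#' @param traits numeric matrix (accessions x traits) with row names.
#' @param n_clusters number of groups to cut (default 4).
#' @return A list with `labels` (named integer cluster vector), `tree`
#'   (`upgma_tree`), `distance` (the trait distance matrix) and
#'   `standardized`.
#' @export
morph_cluster <- function(traits, n_clusters = 4L) {
  z <- standardize_traits(traits)
  if (nrow(z) < 2L) stop("need at least 2 accessions")
  if (n_clusters < 1L || n_clusters > nrow(z))
    stop("n_clusters must be between 1 and the number of accessions")
  d <- as.matrix(stats::dist(z))
  tree <- upgma(d)
  labels <- stats::cutree(as.hclust(tree), k = n_clusters)
  list(labels = labels, tree = tree, distance = d, standardized = z)
}
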