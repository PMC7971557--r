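#' PCA variance-explained fractions
#'
#' Eigenvalue fractions of the covariance of the (centered) z matrix, with
#' the cumulative fraction, for reporting how much of the phenotypic
#' variance the metabolome captures.
#'
#' @param z a `zscore_matrix` or numeric samples-x-variables matrix.
#' @param n_components how many leading components to report (default all).
#' @return data.frame with `component`, `fraction`, `cumulative`.
#' @export
pca_variance_explained <- function(z, n_components = NULL) {
  if (inherits(z, "zscore_matrix")) z <- z$z
  if (nrow(z) < 2L) stop_field("z", "needs >= 2 samples")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components %||% length(frac), length(frac))
  data.frame(component = seq_len(k), fraction = frac[seq_len(k)],
             cumulative = cumsum(frac)[seq_len(k)])
}

#' Ward/Euclidean dendrogram
#'
#' Agglomerative clustering minimizing Ward's increase in within-cluster
#' sum of squares on Euclidean distances (hclust `ward.D2`); merge heights
#' are non-decreasing.
#'
#' @param z a `zscore_matrix` or numeric matrix.
#' @param axis cluster `"samples"` (rows) or `"metabolites"` (columns).
#' @return An `hclust` object.
#' @seealso [write_newick()] to export the merge tree as Newick text.
#' @export
ward_dendrogram <- function(z, axis = c("samples", "metabolites")) {
  if (inherits(z, "zscore_matrix")) z <- z$z
  axis <- match.arg(axis)
  m <- if (axis == "metabolites") t(z) else z
  if (nrow(m) < 2L) stop_field("z", "needs >= 2 items to cluster")
  hclust(dist(m, method = "euclidean"), method = "ward.D2")
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object (e.g. from [ward_dendrogram()]).
#' @param path file to write; the Newick string is also returned invisibly.
#' @export
write_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Permutation importance from a bagged tree ensemble (mean decrease in
#' accuracy)
#'
#' Ranks variables by their ability to distinguish the treatment groups:
#' for each tree the out-of-bag accuracy is compared with the accuracy
#' after permuting one variable's out-of-bag values, and the drops are
#' averaged over trees (unscaled). Backed by a random forest classifier.
#'
#' @param z a `zscore_matrix` or numeric samples-x-variables matrix.
#' @param groups labels per sample (from the `zscore_matrix` if omitted).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; fixed seed gives a fixed result.
#' @return list with `mda` (named per-variable mean decrease in accuracy),
#'   `n_trees` and `seed`.
#' @export
ensemble_mda <- function(z, groups = NULL, n_trees = 500L, seed = 1L) {
  if (inherits(z, "zscore_matrix")) {
    groups <- groups %||% unname(z$group)
    z <- z$z
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_field("groups", "needs >= 2 classes")
  if (any(table(groups) < 4L))
    stop_field("groups", "needs >= 4 samples per group")
  check_number(n_trees, "n_trees", lower = 1, integer = TRUE)
  rf <- with_seed(seed,
    randomForest::randomForest(x = as.data.frame(z), y = groups,
                               ntree = n_trees, importance = TRUE))
  mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  list(mda = setNames(as.numeric(mda), colnames(z)),
       n_trees = as.integer(n_trees), seed = as.integer(seed))
}
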