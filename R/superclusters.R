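#' k-NN superclusters of coordinated metabolites
#'
#' Identifies superclusters — sets of metabolites that change in
#' coordinated ways and may span many biochemical pathways — from each
#' metabolite's z-score profile across samples. A k-nearest-neighbor graph
#' (Euclidean distance between profiles, symmetrized by union) restricts
#' which clusters may merge; merging is agglomerative under Ward's
#' criterion (minimum increase in within-cluster sum of squares, the same
#' objective the dendrograms use) until exactly `n_clusters` remain. If
#' the graph runs out of connecting edges before the target count is
#' reached, the cheapest unconstrained merge is used. Ties break
#' deterministically on the smaller member index, so the partition is
#' reproducible for a fixed input.
#'
#' @param z a `zscore_matrix` or a samples-x-metabolites matrix; profiles
#'   are the columns.
#' @param k_neighbors neighbors per metabolite in the graph (default 10).
#' @param n_clusters number of superclusters to return (default 10).
#' @return Object of class `supercluster_partition`: `assignment` (named
#'   integer, cluster id per metabolite) and `members` (list of metabolite
#'   name vectors). Cluster ids are ordered by first member appearance.
#' @export
knn_superclusters <- function(z, k_neighbors = 10L, n_clusters = 10L) {
  if (inherits(z, "zscore_matrix")) z <- z$z
  profiles <- t(z)                       # metabolites x samples
  m <- nrow(profiles)
  check_number(k_neighbors, "k_neighbors", lower = 1, integer = TRUE)
  check_number(n_clusters, "n_clusters", lower = 1, integer = TRUE)
  if (n_clusters > m)
    stop_field("n_clusters", "exceeds the number of metabolites")
  ids <- rownames(profiles) %||% sprintf("m%d", seq_len(m))

  D2 <- as.matrix(dist(profiles, method = "euclidean"))^2
  diag(D2) <- Inf
  k <- min(k_neighbors, m - 1L)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    nb <- order(D2[i, ], seq_len(m))[seq_len(k)]  # secondary key: index
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)

  # agglomerative Ward-criterion merging constrained to graph edges;
  # D2 holds squared Ward-updated distances, cost = ninj/(ni+nj) * d2
  active <- rep(TRUE, m)
  size <- rep(1L, m)
  members <- as.list(seq_len(m))
  n_active <- m
  while (n_active > n_clusters) {
    cost <- outer(size, size, function(a, b) a * b / (a + b)) * D2
    masked <- cost
    masked[!adj] <- Inf
    if (all(is.infinite(masked[active, active]))) masked <- cost  # exhausted
    masked[!active, ] <- Inf; masked[, !active] <- Inf
    pick <- which.min(masked)            # first (smallest index) at ties
    j <- ((pick - 1L) %/% m) + 1L
    i <- ((pick - 1L) %% m) + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    ni <- size[i]; nj <- size[j]
    newd <- ((ni + size) * D2[i, ] + (nj + size) * D2[j, ] -
               size * D2[i, j]) / (ni + nj + size)     # Lance-Williams, Ward
    D2[i, ] <- newd; D2[, i] <- newd; D2[i, i] <- Inf
    adj[i, ] <- adj[i, ] | adj[j, ]
    adj[, i] <- adj[, i] | adj[, j]
    adj[i, i] <- FALSE
    active[j] <- FALSE
    D2[j, ] <- Inf; D2[, j] <- Inf
    adj[j, ] <- FALSE; adj[, j] <- FALSE
    size[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer()
    n_active <- n_active - 1L
  }
  keep <- which(active)
  keep <- keep[order(vapply(members[keep], min, 1L))]
  assignment <- integer(m)
  for (cc in seq_along(keep)) assignment[members[[keep[cc]]]] <- cc
  structure(
    list(assignment = setNames(assignment, ids),
         members = lapply(keep, function(i) ids[sort(members[[i]])])),
    class = "supercluster_partition")
}

#' @export
print.supercluster_partition <- function(x, ...) {
  cat(sprintf("<supercluster_partition> %d metabolites in %d clusters\n",
              length(x$assignment), length(x$members)))
  cat("sizes:", paste(lengths(x$members), collapse = ", "), "\n")
  invisible(x)
}

#' Rank superclusters by threshold-gated summed VIP
#'
#' Each cluster scores the sum of member VIPs at or above `vip_threshold`;
#' ranking is by that score, with the sum of positive MDA scores as the
#' secondary key and cluster id as a deterministic fallback. The impact
#' fraction is each cluster's share of the total score; if every score is
#' zero the fractions are uniform (with a warning).
#'
#' @param clusters a `supercluster_partition` from [knn_superclusters()].
#' @param vip named per-metabolite VIP scores.
#' @param mda named per-metabolite mean-decrease-in-accuracy scores.
#' @param vip_threshold minimum VIP for a member to count (default 1.0).
#' @return data.frame: `cluster`, `n_members`, `vip_sum`, `mda_sum`,
#'   `impact_fraction`, `mean_z`, `sd_z` (the latter two NA until filled by
#'   [cluster_summary()]), `rank`; sorted by rank.
#' @export
rank_clusters <- function(clusters, vip, mda, vip_threshold = 1.0) {
  stopifnot(inherits(clusters, "supercluster_partition"))
  check_number(vip_threshold, "vip_threshold", lower = 0)
  if (is.null(names(vip)) || is.null(names(mda)))
    stop_field("vip/mda", "must be named by metabolite")
  score <- vapply(clusters$members, function(mm) {
    v <- vip[mm]
    if (anyNA(v)) stop_field("vip", "missing VIP for a cluster member")
    sum(v[v >= vip_threshold])
  }, 1)
  mda_sum <- vapply(clusters$members, function(mm) {
    d <- mda[mm]
    if (anyNA(d)) stop_field("mda", "missing MDA for a cluster member")
    sum(d[d > 0])
  }, 1)
  total <- sum(score)
  if (total > 0) {
    frac <- score / total
  } else {
    warning("all cluster scores are zero; reporting uniform impact fractions")
    frac <- rep(1 / length(score), length(score))
  }
  out <- data.frame(cluster = seq_along(score),
                    n_members = lengths(clusters$members),
                    vip_sum = score, mda_sum = mda_sum,
                    impact_fraction = frac,
                    mean_z = NA_real_, sd_z = NA_real_)
  o <- order(-out$vip_sum, -out$mda_sum, out$cluster)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean and SD of a cluster's treated-sample response
#'
#' Summarizes one supercluster as mean +/- SD of its members' mean treated
#' z values (SD over members, n-1 denominator; a single member reports 0).
#'
#' @param members character vector of member metabolite names.
#' @param zmat a `zscore_matrix`.
#' @param treated_group optional explicit treated group label.
#' @return list with `mean_z`, `sd_z`, `n_members`.
#' @export
cluster_summary <- function(members, zmat, treated_group = NULL) {
  if (length(members) < 1L) stop_field("members", "cluster is empty")
  mz <- mean_treated_z(zmat, treated_group)[members]
  if (anyNA(mz)) stop_field("members", "unknown metabolite in cluster")
  list(mean_z = mean(mz),
       sd_z = if (length(mz) > 1L) sd(mz) else 0,
       n_members = length(members))
}
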