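make_results <- function(vip, pathway, mean_z, significant,
                         metabolite = sprintf("m%02d", seq_along(vip))) {
  data.frame(metabolite = metabolite, pathway = pathway, mean_z = mean_z,
             U = 1, U_p = 0.01, t_p = 0.01, fdr = 0.01, q = 0.01,
             direction = ifelse(mean_z > 0, "up", "down"),
             vip = vip, significant = significant)
}

test_that("pathway VIP aggregation ranks by summed VIP with deterministic ties", {
  res <- make_results(vip = c(2.0, 1.5, 1.2), pathway = c("A", "A", "B"),
                      mean_z = c(-3, -1, 2), significant = TRUE)
  agg <- aggregate_pathway_vip(res)
  expect_equal(agg$pathway, c("A", "B"))
  expect_equal(agg$vip_sum, c(3.5, 1.2))
  expect_equal(agg$rank, 1:2)
  expect_equal(agg$direction, c("decreased", "increased"))
  empty <- aggregate_pathway_vip(transform(res, significant = FALSE))
  expect_equal(nrow(empty), 0)
  # no double counting: pathway sums add up to the significant VIP total
  set.seed(4)
  res2 <- make_results(vip = runif(30, 0.5, 2),
                       pathway = sample(LETTERS[1:5], 30, TRUE),
                       mean_z = rnorm(30),
                       significant = runif(30) < 0.6)
  agg2 <- aggregate_pathway_vip(res2)
  expect_equal(sum(agg2$vip_sum), sum(res2$vip[res2$significant]),
               tolerance = 1e-12)
})

test_that("direction classification covers all sign patterns and ignores order", {
  expect_equal(classify_pathway_direction(c(3, 1)), "increased")
  expect_equal(classify_pathway_direction(c(-2, -4)), "decreased")
  expect_equal(classify_pathway_direction(c(3, -1)), "mixed")
  expect_equal(classify_pathway_direction(c(-1, 3)), "mixed")
  expect_error(classify_pathway_direction(numeric(0)), ">= 1")
})

test_that("changed-metabolite counts print the published percentages", {
  expect_equal(count_changed(202, 401)$percent, 50L)
  expect_equal(count_changed(54, 401)$percent, 13L)
  expect_equal(count_changed(0, 401)$percent, 0L)
  expect_error(count_changed(10, 5), "total")
})

test_that("planted pathway effects occupy the top pathway ranks", {
  hits <- vapply(1:100, function(s) {
    mets <- data.frame(name = sprintf("m%03d", 1:60),
                       pathway = rep(sprintf("pw%02d", 1:12), each = 5),
                       effect_z = c(rep(4, 15), rep(0, 45)))
    spec <- metabolome_spec(mets, seed = s)
    z <- control_zscore(log2_transform(simulate_metabolome(spec)), "control")
    st <- significance_filter(univariate_stats(z), plsda_fit(z)$vip)
    agg <- aggregate_pathway_vip(st)
    all(c("pw01", "pw02", "pw03") %in% agg$pathway[1:3])
  }, TRUE)
  expect_gte(sum(hits), 90)
})

test_that("k-NN superclustering recovers opposite-sign blocks and partitions exactly", {
  set.seed(5)
  n <- 12
  up <- matrix(rnorm(10 * n, 3, 0.3), 10, n)
  dn <- matrix(rnorm(10 * n, -3, 0.3), 10, n)
  z <- t(rbind(up, dn))   # samples x metabolites
  colnames(z) <- sprintf("m%02d", 1:20)
  part <- knn_superclusters(z, k_neighbors = 5, n_clusters = 2)
  expect_equal(unname(part$assignment), rep(1:2, each = 10))
  # identical profiles, single cluster
  zz <- matrix(1, 4, 5, dimnames = list(NULL, letters[1:5]))
  p1 <- knn_superclusters(zz, k_neighbors = 2, n_clusters = 1)
  expect_equal(length(p1$members), 1)
  # partition property on arbitrary data
  set.seed(8)
  za <- matrix(rnorm(200), 8, 25, dimnames = list(NULL, sprintf("v%d", 1:25)))
  pa <- knn_superclusters(za, k_neighbors = 4, n_clusters = 6)
  expect_equal(sort(unlist(pa$members)), sort(colnames(za)))
  expect_equal(length(unlist(pa$members)), 25)
  expect_error(knn_superclusters(za, n_clusters = 30), "exceeds")
})

test_that("cluster ranking computes threshold-gated impact fractions", {
  part <- structure(list(assignment = setNames(c(1, 1, 2, 2), letters[1:4]),
                         members = list(c("a", "b"), c("c", "d"))),
                    class = "supercluster_partition")
  vip <- c(a = 5, b = 3, c = 2, d = 0.5)
  mda <- c(a = 0.1, b = 0.05, c = 0.02, d = -0.01)
  rk <- rank_clusters(part, vip, mda, vip_threshold = 1)
  expect_equal(rk$vip_sum, c(8, 2))
  expect_equal(rk$impact_fraction, c(0.8, 0.2))
  expect_equal(sum(rk$impact_fraction), 1)
  # cluster entirely below threshold scores zero and ranks last
  rk2 <- rank_clusters(part, c(a = 5, b = 3, c = 0.2, d = 0.5),
                       mda, vip_threshold = 1)
  expect_equal(rk2$vip_sum[rk2$rank == 2], 0)
  expect_warning(
    rk0 <- rank_clusters(part, c(a = .1, b = .1, c = .1, d = .1), mda, 1),
    "uniform")
  expect_equal(rk0$impact_fraction, c(0.5, 0.5))
})

test_that("cluster summaries report member-level mean and SD of treated z", {
  sp <- ten_cluster_spec(seed = 3)
  z <- control_zscore(log2_transform(simulate_metabolome(sp)), "control")
  cs <- cluster_summary(sprintf("met%03d", 1:10), z)
  expect_equal(cs$n_members, 10)
  # planted +3.2, recovered with the ~1.13 small-sample inflation
  expect_gt(cs$mean_z, 2.5)
  expect_lt(cs$mean_z, 4.6)
  one <- cluster_summary("met001", z)
  expect_equal(one$sd_z, 0)
  # arithmetic contract: members with mean z {3, 5} -> 4 +/- sqrt(2)
  fake <- structure(list(
    z = rbind(matrix(0, 3, 2), matrix(rep(c(3, 5), each = 3), 3, 2)),
    group = rep(c("c", "t"), each = 3), control_group = "c",
    pathway = NULL, dropped = character()), class = "zscore_matrix")
  colnames(fake$z) <- c("x", "y")
  s <- cluster_summary(c("x", "y"), fake)
  expect_equal(s$mean_z, 4)
  expect_equal(s$sd_z, sqrt(2), tolerance = 1e-12)
})
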