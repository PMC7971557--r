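test_that("Mann-Whitney U matches exhaustive enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)            # 2/20 arrangements as extreme
  expect_true(r$exact)
  # random tie-free datasets: exact p equals the enumeration oracle
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    got <- mann_whitney_u(x, y)
    want <- mw_enumerate(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles identical groups and input contracts", {
  r <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))   # ties -> approx
  expect_gt(r$p, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), ">= 2")
  expect_error(mann_whitney_u(1, 1:3), ">= 2")
})

test_that("ANOVA F and protected LSD behave on degenerate, separated, and hand-computed cases", {
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  r0 <- anova_fisher_lsd(same)
  expect_equal(r0$F, 0); expect_equal(r0$p, 1)
  expect_true(all(is.na(r0$lsd_p)))

  set.seed(1)
  sep <- list(g1 = rnorm(3, 0, 1e-3), g2 = rnorm(3, 0, 1e-3),
              g3 = rnorm(3, 10, 1e-3))
  rs <- anova_fisher_lsd(sep)
  expect_lt(rs$p, 1e-6)
  expect_lt(rs$lsd_p["g3", "g1"], 1e-6)
  expect_lt(rs$lsd_p["g3", "g2"], 1e-6)
  expect_gt(rs$lsd_p["g1", "g2"], 0.05)

  # hand-computed 3x3: means 2,3,7, SSB = 42, SSW = 6 -> F = 21
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  rh <- anova_fisher_lsd(g)
  expect_equal(rh$F, 21, tolerance = 1e-12)
  expect_equal(rh$df, c(2, 6))
  # independent route: aov on the same data
  df <- data.frame(y = unlist(g), grp = rep(names(g), each = 3))
  expect_equal(rh$F, summary(aov(y ~ grp, df))[[1]]$`F value`[1],
               tolerance = 1e-10)
  expect_error(anova_fisher_lsd(list(1:3, 1:3)), ">= 3")
  expect_error(anova_fisher_lsd(list(1:3, 1:3, 5)), ">= 2")
})

test_that("BH adjustment matches the hand-computed step-up and its edge cases", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey q reduces to BH at pi0 = 1, estimates pi0 on uniform nulls, stays monotone", {
  set.seed(7)
  p <- runif(50)
  expect_equal(storey_q(p, pi0 = 1)$q, bh_fdr(p), tolerance = 1e-12)
  set.seed(123)
  pu <- runif(1000)
  est <- storey_q(pu)
  expect_gte(est$pi0, 0.85); expect_lte(est$pi0, 1.0)
  o <- order(p)
  expect_true(all(diff(storey_q(p)$q[o]) >= -1e-12))
  expect_warning(storey_q(runif(5)), "pi0 = 1")
})

test_that("univariate stats table is coherent: FDR >= p, direction matches sign", {
  z <- control_zscore(log2_transform(simulate_metabolome(
    planted_spec(p = 30, k = 6, effect = -4, seed = 9))), "control")
  st <- univariate_stats(z)
  expect_equal(nrow(st), 30)
  expect_true(all(st$fdr >= st$t_p - 1e-12))
  expect_true(all(st$q >= 0 & st$q <= 1))
  expect_true(all(st$direction[st$mean_z < 0] == "down"))
  expect_true(all(st$fdr[1:6] < 0.05))   # planted block found
})

test_that("significance filter applies the three thresholds and is monotone", {
  res <- data.frame(metabolite = c("m1", "m2"), pathway = "p",
                    mean_z = c(-3, 1), U = c(0, 10), U_p = c(0.01, 0.2),
                    t_p = c(0.01, 0.2), fdr = c(0.02, 0.2), q = c(0.02, 0.2),
                    direction = c("down", "up"))
  out <- significance_filter(res, vip = c(1.2, 2.0))
  expect_identical(out$significant, c(TRUE, FALSE))
  all_pass <- significance_filter(res, vip = c(1.2, 2.0),
                                  fdr_max = 1, vip_min = 0, p_max = 1)
  expect_true(all(all_pass$significant))
  # relaxing any threshold never shrinks the significant set
  set.seed(3)
  res2 <- data.frame(metabolite = sprintf("m%d", 1:50), pathway = "p",
                     mean_z = rnorm(50), U = 1, U_p = runif(50),
                     t_p = runif(50), fdr = runif(50), q = runif(50),
                     direction = "up")
  vip <- runif(50, 0, 2)
  base <- significance_filter(res2, vip, 0.3, 0.9, 0.3)$significant
  for (relax in list(c(0.6, 0.9, 0.3), c(0.3, 0.4, 0.3), c(0.3, 0.9, 0.6))) {
    rel <- significance_filter(res2, vip, relax[1], relax[2], relax[3])$significant
    expect_true(all(rel[base]))
  }
})

test_that("filter recovers planted effects with few false positives at study scale", {
  mets <- data.frame(name = sprintf("met%03d", 1:400),
                     pathway = rep(sprintf("pw%02d", 1:40), each = 10),
                     effect_z = c(rep(4, 50), rep(0, 350)))
  spec <- metabolome_spec(mets, n_control = 8, n_treated = 8, seed = 21)
  z <- control_zscore(log2_transform(simulate_metabolome(spec)), "control")
  st <- univariate_stats(z)
  fit <- plsda_fit(z, n_components = 2)
  st <- significance_filter(st, fit$vip)
  true_hits <- sum(st$significant[1:50])
  false_hits <- sum(st$significant[51:400])
  expect_gte(true_hits, 45)
  expect_lte(false_hits, ceiling(0.05 * 350 + 2 * sqrt(350 * 0.05 * 0.95)))
})

test_that("normal approximation with continuity correction tracks the exact Mann-Whitney p", {
  set.seed(11)
  gaps <- replicate(100, {
    x <- rnorm(8); y <- rnorm(8)
    pe <- mann_whitney_u(x, y)$p
    pa <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    abs(pe - pa)
  })
  # the deterministic worst case over all U at n = 8+8 is 0.0109 (U = 24)
  expect_lt(max(gaps), 0.011)
})
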