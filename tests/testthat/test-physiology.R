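test_that("RER is the per-interval gas ratio, averaged per animal then per group", {
  tr <- data.frame(animal = rep(c("a1", "a2"), each = 3),
                   group = "saline", start_min = rep(c(0, 13, 26), 2),
                   vo2 = c(5000, 5200, 5400, 4800, 5000, 5200),
                   vco2 = NA, beam_breaks = 0)
  tr$vco2 <- 0.7 * tr$vo2
  r <- compute_rer(tr)
  expect_equal(r$per_interval$rer, rep(0.7, 6))
  expect_equal(r$per_group$mean_rer, 0.7)
  tr$vco2 <- tr$vo2
  expect_equal(compute_rer(tr)$per_group$mean_rer, 1.0)
  # scale invariance: multiplying both gas rates leaves RER unchanged
  tr2 <- transform(tr, vo2 = vo2 * 3, vco2 = vco2 * 3)
  expect_equal(compute_rer(tr2)$per_group$mean_rer, 1.0)
  tr$vo2[1] <- 0
  expect_error(compute_rer(tr), "vo2")
})

test_that("averaging order matters: ratio of group means differs from mean per-interval RER", {
  # the published group means 4324/5302 give 0.816, not the per-interval 0.84
  expect_equal(4324 / 5302, 0.8156, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(4324 / 5302, 0.84, tolerance = 0.01)))
  # constructed case where the two orders disagree
  tr <- data.frame(animal = "a1", group = "g", start_min = c(0, 13),
                   vo2 = c(1000, 4000), vco2 = c(900, 2800), beam_breaks = 0)
  r <- compute_rer(tr)
  expect_equal(r$per_group$mean_rer, mean(c(0.9, 0.7)))
  expect_false(isTRUE(all.equal(r$per_group$mean_rer,
                                sum(tr$vco2) / sum(tr$vo2))))
})

test_that("percent change reproduces published table values and composes", {
  expect_equal(percent_change(5302, 1382)$percent, -74L)
  expect_equal(percent_change(4324, 1034)$percent, -76L)
  expect_equal(percent_change(650, 180)$percent, -72L)
  expect_equal(percent_change(742, 27)$percent, -96L)
  expect_equal(percent_change(5, 5)$percent, 0L)
  expect_error(percent_change(0, 5), "baseline")
  # applying the raw percent to the baseline reproduces the treated mean
  pc <- percent_change(5302, 1382)
  expect_equal(5302 * (1 + pc$percent_raw / 100), 1382, tolerance = 1e-9)
})

test_that("Lusk heat matches the published saline mean and scales linearly", {
  h <- lusk_heat(5302, 0.84, 0.025)
  expect_equal(h, 643, tolerance = 0.01)       # within Table band 650 +/- 84
  expect_lt(abs(h - 650), 84)
  expect_equal(lusk_heat(0, 0.84, 0.025), 0)
  expect_equal(lusk_heat(5302, 0.84, 0.050), 2 * h)
  expect_warning(lusk_heat(5302, 1.5, 0.025), "clip")
  expect_error(lusk_heat(5302, 0.84, NULL), "mass")
})

test_that("age equivalence follows the piecewise schedule, continuously and monotonically", {
  expect_equal(age_equivalent(8), 35)
  expect_equal(age_equivalent(1), 12)
  expect_equal(age_equivalent(6), 30)
  expect_equal(age_equivalent(2), 18)
  expect_equal(age_equivalent(0.5), 6)          # linear within month 1
  grid <- seq(0.1, 24, by = 0.1)
  vals <- age_equivalent(grid)
  expect_true(all(diff(vals) > 0))
  expect_lt(max(abs(diff(vals))), 1.21)         # no jumps beyond slope*step
  expect_error(age_equivalent(0), "> 0")
})

test_that("PBRS totals six 3-point items with range 0 to 12", {
  expect_equal(pbrs_total(rep(0, 6)), 0L)
  expect_equal(pbrs_total(rep(2, 6)), 12L)
  expect_equal(pbrs_total(c(2, 2, 2, 2, 1, 1)), 10L)
  expect_error(pbrs_total(c(2, 2, 2, 2, 1)), "six")
  expect_error(pbrs_total(c(3, 0, 0, 0, 0, 0)), "0, 1 or 2")
})

test_that("dose-response fit recovers noiseless slopes and tests their difference", {
  doses <- c(0, 0.05, 0.1, 0.15, 0.2)
  f <- rbind(simulate_dose_response(-27.8, 38.4, doses, 6, 0, "F", 1),
             simulate_dose_response(-16.5, 37.9, doses, 6, 0, "M", 2))
  fit <- suppressWarnings(fit_dose_response(f))  # perfect-fit lm warnings
  expect_equal(fit$slopes$beta[fit$slopes$sex == "F"], -27.8, tolerance = 1e-9)
  expect_equal(fit$slopes$beta[fit$slopes$sex == "M"], -16.5, tolerance = 1e-9)
  expect_lt(fit$interaction_p, 1e-10)
  expect_equal(fit$interaction_df[1], 1)
  # identical data for both sexes: interaction exactly null
  base <- simulate_dose_response(-20, 38, doses, 4, 0.3, "F", 5)
  same <- rbind(base, transform(base, sex = "M"))
  fit0 <- fit_dose_response(same)
  expect_equal(fit0$interaction_F, 0, tolerance = 1e-9)
  expect_equal(fit0$interaction_p, 1, tolerance = 1e-9)
  expect_error(fit_dose_response(data.frame(sex = "F", dose = 1, response = 1)),
               "two sexes")
})

test_that("phase-window summaries report deltas and the MIA baseline offset", {
  # constant series: all deltas zero
  const <- data.frame(animal = rep(c("a", "b"), each = 10),
                      group = "ctrl", day = rep(-2:7, 2),
                      temperature = 36.3)
  ps <- phase_summary(const, list(baseline = c(-2, 0), rebound = c(5, 7)))
  expect_equal(ps$delta, c(0, 0))
  expect_equal(ps$p_vs_baseline[ps$window == "rebound"], 1)
  # two groups offset by the published 0.5 degrees at baseline
  two <- rbind(const,
               transform(const, group = "MIA", temperature = 35.8))
  ps2 <- phase_summary(two, list(baseline = c(-2, 0), rebound = c(5, 7)))
  b <- ps2[ps2$window == "baseline", ]
  expect_equal(b$mean[b$group == "ctrl"] - b$mean[b$group == "MIA"], 0.5,
               tolerance = 1e-12)
  expect_error(phase_summary(const, list(baseline = c(-2, 0),
                                         late = c(20, 30))), "empty")
})

test_that("synthetic rebound amplitude is recovered from the triphasic template", {
  deltas <- vapply(1:20, function(s) {
    tmp <- simulate_temperature(n_animals = 6, rebound_delta = 0.8, seed = s)
    ps <- phase_summary(tmp, list(baseline = c(-3, 0), rebound = c(6, 14)))
    ps$delta[ps$window == "rebound"]
  }, 1)
  expect_lt(abs(mean(deltas) - 0.8), 0.15)
})
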