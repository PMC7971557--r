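#' Specify a synthetic indirect-calorimetry experiment
#'
#' Two-group CLAMS-style design: per-group means and SDs for VO2, VCO2
#' (ml/kg/hr) and locomotor activity (beam breaks per interval), recorded
#' in 13-minute cycles over a 3-hour horizon. Treated animals run at the
#' saline-like baseline until `drop_minute`, then drop to the stated
#' post-injection means. Between-animal SDs are the Table-style group SDs;
#' within-animal interval noise is a separate, smaller SD.
#'
#' @param groups data.frame with columns `group`, `n`, `vo2_mean`,
#'   `vo2_sd`, `vco2_mean`, `vco2_sd`, `activity_mean`, `activity_sd`, and
#'   logical `treated`.
#' @param baseline list with `vo2`, `vco2`, `activity` pre-injection means
#'   used for treated animals before `drop_minute`.
#' @param interval_min cycle length in minutes (default 13).
#' @param horizon_min recording horizon (default 182 = 14 cycles ~ 3 h).
#' @param drop_minute first minute at which treated animals are at their
#'   post-injection level (default 26).
#' @param within_cv within-animal interval coefficient of variation for the
#'   gas rates (default 0.05).
#' @param seed integer seed.
#' @return object of class `calorimetry_spec`.
#' @export
calorimetry_spec <- function(groups, baseline = NULL, interval_min = 13,
                             horizon_min = 182, drop_minute = 26,
                             within_cv = 0.05, seed = 1L) {
  need <- c("group", "n", "vo2_mean", "vo2_sd", "vco2_mean", "vco2_sd",
            "activity_mean", "activity_sd", "treated")
  if (!is.data.frame(groups) || !all(need %in% names(groups)))
    stop_field("groups", paste("needs columns:", paste(need, collapse = ", ")))
  num <- c("vo2_mean", "vco2_mean", "activity_mean")
  if (any(as.matrix(groups[num]) < 0))
    stop_field("groups", "means must be non-negative")
  if (any(as.matrix(groups[c("vo2_sd", "vco2_sd", "activity_sd")]) < 0))
    stop_field("groups", "SDs must be >= 0")
  if (any(groups$n < 1)) stop_field("n", "needs >= 1 animal per group")
  check_number(interval_min, "interval_min", lower = 1)
  check_number(within_cv, "within_cv", lower = 0)
  structure(list(groups = groups,
                 baseline = baseline %||%
                   list(vo2 = max(groups$vo2_mean),
                        vco2 = max(groups$vco2_mean),
                        activity = max(groups$activity_mean)),
                 interval_min = interval_min, horizon_min = horizon_min,
                 drop_minute = drop_minute, within_cv = within_cv,
                 seed = as.integer(seed)),
            class = "calorimetry_spec")
}

#' Default calorimetry spec at the published acute-response scale
#'
#' Saline VO2 5302 +/- 710 and VCO2 4324 +/- 647 ml/kg/hr with activity
#' 742 +/- 442 beam breaks; ATP-treated animals drop to 1382 +/- 325,
#' 1034 +/- 226 and 27 +/- 16 from 26 minutes post-infusion; n = 6 per
#' group.
#'
#' @param n animals per group (default 6).
#' @param seed integer seed.
#' @return a [calorimetry_spec()].
#' @export
acute_calorimetry_spec <- function(n = 6L, seed = 1L) {
  calorimetry_spec(
    data.frame(
      group = c("saline", "ATP"),
      n = n,
      vo2_mean = c(5302, 1382), vo2_sd = c(710, 325),
      vco2_mean = c(4324, 1034), vco2_sd = c(647, 226),
      activity_mean = c(742, 27), activity_sd = c(442, 16),
      treated = c(FALSE, TRUE), stringsAsFactors = FALSE),
    baseline = list(vo2 = 5302, vco2 = 4324, activity = 742),
    seed = seed)
}

#' Simulate calorimetry traces
#'
#' One trace per animal in 13-minute intervals. Animal-level gas means are
#' drawn from the group mean/SD; interval values add within-animal noise
#' (`within_cv` of the mean). With all SDs zero every interval equals the
#' spec mean exactly. Activity counts are non-negative rounded normals.
#'
#' @param spec a [calorimetry_spec()].
#' @return data.frame of intervals: `animal`, `group`, `start_min`, `vo2`,
#'   `vco2`, `beam_breaks`.
#' @export
simulate_calorimetry <- function(spec) {
  if (!inherits(spec, "calorimetry_spec"))
    stop_field("spec", "must be a calorimetry_spec")
  starts <- seq(0, spec$horizon_min - spec$interval_min,
                by = spec$interval_min)
  out <- list()
  with_seed(spec$seed, {
    for (gi in seq_len(nrow(spec$groups))) {
      g <- spec$groups[gi, ]
      for (ai in seq_len(g$n)) {
        vo2_a <- rnorm(1, g$vo2_mean, g$vo2_sd)
        vco2_a <- rnorm(1, g$vco2_mean, g$vco2_sd)
        act_a <- rnorm(1, g$activity_mean, g$activity_sd)
        post <- starts >= spec$drop_minute
        lvl_vo2 <- if (g$treated)
          ifelse(post, vo2_a, spec$baseline$vo2) else rep(vo2_a, length(starts))
        lvl_vco2 <- if (g$treated)
          ifelse(post, vco2_a, spec$baseline$vco2) else rep(vco2_a, length(starts))
        lvl_act <- if (g$treated)
          ifelse(post, act_a, spec$baseline$activity) else rep(act_a, length(starts))
        vo2 <- pmax(lvl_vo2 + rnorm(length(starts), 0,
                                    spec$within_cv * g$vo2_mean), 1)
        vco2 <- pmax(lvl_vco2 + rnorm(length(starts), 0,
                                      spec$within_cv * g$vco2_mean), 1)
        act <- pmax(round(lvl_act), 0)
        out[[length(out) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", g$group, ai), group = g$group,
          start_min = starts, vo2 = vo2, vco2 = vco2, beam_breaks = act,
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, out)
}

#' Simulate a dose-response table
#'
#' `response = intercept + slope * dose + N(0, noise_sd)` per animal.
#'
#' @param slope_beta slope (e.g. degrees C per umol/g ATP).
#' @param intercept response at dose 0 (e.g. baseline temperature).
#' @param doses vector of non-negative doses; each dose is given to
#'   `n_per_dose` animals.
#' @param n_per_dose animals per dose (>= 2).
#' @param noise_sd residual SD.
#' @param sex label stored alongside (default `"F"`).
#' @param seed integer seed.
#' @return data.frame with `sex`, `dose`, `response`.
#' @export
simulate_dose_response <- function(slope_beta, intercept, doses,
                                   n_per_dose = 6L, noise_sd = 0.5,
                                   sex = "F", seed = 1L) {
  if (length(doses) < 1L) stop_field("doses", "empty dose list")
  if (any(doses < 0)) stop_field("doses", "must be non-negative")
  check_number(n_per_dose, "n_per_dose", lower = 2, integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  dose <- rep(doses, each = n_per_dose)
  resp <- with_seed(seed,
    intercept + slope_beta * dose + rnorm(length(dose), 0, noise_sd))
  data.frame(sex = sex, dose = dose, response = resp,
             stringsAsFactors = FALSE)
}

#' Specify and simulate longitudinal temperature series
#'
#' Generates daily rectal-temperature series following a phase template:
#' flat baseline, a day-1 spike, a day-2..4 dip, an optional sustained
#' rebound window, and return to baseline afterwards. Used to emulate the
#' triphasic innate-immune temperature response, including the MIA rebound
#' of +0.8 degrees C over days 6-14 and the 0.5 degree MIA baseline
#' offset.
#'
#' @param n_animals animals per group.
#' @param baseline_temp baseline temperature (degrees C).
#' @param spike_delta day-1 change (degrees C).
#' @param dip_delta day 2-4 change (degrees C).
#' @param rebound_delta sustained rebound amplitude (degrees C).
#' @param rebound_days `c(first, last)` day window of the rebound.
#' @param days vector of observation days (challenge at day 0; day <= 0 is
#'   baseline).
#' @param noise_sd observation SD (default 0.4, rectal-probe plus
#'   biological variation).
#' @param group group label.
#' @param seed integer seed.
#' @return data.frame: `animal`, `group`, `day`, `temperature`.
#' @export
simulate_temperature <- function(n_animals = 6L, baseline_temp = 35.5,
                                 spike_delta = 0.6, dip_delta = -0.8,
                                 rebound_delta = 0.8,
                                 rebound_days = c(6, 14),
                                 days = -3:28, noise_sd = 0.4,
                                 group = "MIA_polyIC", seed = 1L) {
  check_number(n_animals, "n_animals", lower = 1, integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (rebound_days[1L] > rebound_days[2L])
    stop_field("rebound_days", "window must be ordered")
  template <- function(day) {
    ifelse(day <= 0, 0,
      ifelse(day <= 1, spike_delta,
        ifelse(day <= 4, dip_delta,
          ifelse(day >= rebound_days[1L] & day <= rebound_days[2L],
                 rebound_delta, 0))))
  }
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_animals), function(ai) {
      data.frame(animal = sprintf("%s_%02d", group, ai), group = group,
                 day = days,
                 temperature = baseline_temp + template(days) +
                   rnorm(length(days), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  out
}
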