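#' Respiratory exchange ratio from a calorimetry trace set
#'
#' RER = VCO2/VO2 per 13-minute interval. Averaging order matters and is
#' fixed here: per-interval RERs are averaged within each animal, and the
#' group summary is the mean of those per-animal means. (The ratio of group
#' mean gas rates is a different number — e.g. printed group means
#' 4324/5302 = 0.816 versus a per-interval mean RER of 0.84 — so the two
#' must not be conflated.)
#'
#' @param traces data.frame of calorimetry intervals with columns `animal`,
#'   `group`, `start_min`, `vo2`, `vco2`, `beam_breaks`.
#' @param window optional numeric `c(min, max)` of start minutes to keep
#'   (e.g. `c(26, 30)` for the early post-infusion window).
#' @return list with `per_interval` (input rows plus `rer`), `per_animal`
#'   (animal, group, mean rer) and `per_group` (group mean +/- SD of the
#'   per-animal means).
#' @export
compute_rer <- function(traces, window = NULL) {
  traces <- validate_calorimetry(traces)
  if (!is.null(window))
    traces <- traces[traces$start_min >= window[1L] &
                     traces$start_min <= window[2L], , drop = FALSE]
  if (nrow(traces) == 0L) stop_field("window", "no intervals in window")
  traces$rer <- traces$vco2 / traces$vo2
  per_animal <- aggregate(rer ~ animal + group, data = traces, FUN = mean)
  per_group <- do.call(rbind, lapply(split(per_animal, per_animal$group),
    function(d) data.frame(group = d$group[1L], mean_rer = mean(d$rer),
                           sd_rer = if (nrow(d) > 1L) sd(d$rer) else 0,
                           n = nrow(d))))
  rownames(per_group) <- NULL
  list(per_interval = traces, per_animal = per_animal, per_group = per_group)
}

validate_calorimetry <- function(traces) {
  need <- c("animal", "group", "start_min", "vo2", "vco2", "beam_breaks")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop_field("traces", paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(!is.finite(traces$vo2)) || any(traces$vo2 <= 0))
    stop_field("vo2", "must be > 0 for every interval")
  if (any(!is.finite(traces$vco2)) || any(traces$vco2 <= 0))
    stop_field("vco2", "must be > 0 for every interval")
  for (a in split(traces, traces$animal))
    if (anyDuplicated(a$start_min))
      stop_field("start_min", sprintf("duplicate interval times for animal '%s'",
                                      a$animal[1L]))
  traces[order(traces$animal, traces$start_min), , drop = FALSE]
}

#' Percent change of a treated mean versus baseline
#'
#' `100 * (treated - baseline) / baseline`; `percent` is rounded to the
#' nearest integer for reporting (Table-style signed percents), with the
#' unrounded value in `percent_raw`.
#'
#' @param baseline_mean,treated_mean group means; baseline must be non-zero.
#' @return list with `percent` (integer) and `percent_raw`.
#' @examples
#' percent_change(5302, 1382)$percent # -74
#' @export
percent_change <- function(baseline_mean, treated_mean) {
  check_number(baseline_mean, "baseline_mean", allow_zero = FALSE)
  check_number(treated_mean, "treated_mean")
  raw <- 100 * (treated_mean - baseline_mean) / baseline_mean
  list(percent = as.integer(round(raw)), percent_raw = raw)
}

#' Radiated heat by the Lusk equation
#'
#' Indirect-calorimetry heat production: the caloric value of oxygen is
#' `CV = 3.815 + 1.232 * RER` kcal per liter O2 (Lusk), so
#' `heat (cal/hour) = CV * VO2(L/kg/hr) * mass(kg) * 1000`. RER outside the
#' physiologic band `[0.65, 1.05]` is clipped with a warning.
#'
#' @param vo2 oxygen consumption in ml/kg/hr.
#' @param rer respiratory exchange ratio.
#' @param mass body mass in kg (default 0.025, an adult mouse).
#' @return heat in cal/hour.
#' @examples
#' lusk_heat(5302, 0.84, 0.025) # ~ 643 cal/hour
#' @export
lusk_heat <- function(vo2, rer, mass = 0.025) {
  if (any(vo2 < 0)) stop_field("vo2", "must be >= 0")
  if (is.null(mass) || anyNA(mass) || any(mass <= 0))
    stop_field("mass", "body mass in kg is required")
  if (any(rer < 0.65 | rer > 1.05)) {
    warning("RER outside [0.65, 1.05]; clipping to the physiologic band")
    rer <- pmin(pmax(rer, 0.65), 1.05)
  }
  cv <- 3.815 + 1.232 * rer            # kcal per liter O2
  cv * (vo2 / 1000) * mass * 1000
}

#' Human age equivalent of a C57BL/6J mouse
#'
#' Piecewise conversion: the 1st month of mouse life counts 12 human
#' years, the 2nd month 6 years, months 3-6 count 3 years each, and every
#' month thereafter 2.5 years. Fractional months interpolate linearly
#' within the current bracket, so the mapping is continuous and strictly
#' increasing. An 8-month-old mouse is 12 + 6 + 3*4 + 2.5*2 = 35 human
#' years.
#'
#' @param age_months mouse age in months (> 0); vectorized.
#' @return human-equivalent age in years.
#' @examples
#' age_equivalent(8) # 35
#' @export
age_equivalent <- function(age_months) {
  if (!is.numeric(age_months) || anyNA(age_months) || any(age_months <= 0))
    stop_field("age_months", "must be > 0")
  rate_per_month <- c(12, 6, 3, 3, 3, 3)  # months 1..6; 2.5 after
  one <- function(a) {
    full <- floor(a); frac <- a - full
    yrs <- sum(rate_per_month[seq_len(min(full, 6L))])
    if (full > 6L) yrs <- yrs + 2.5 * (full - 6L)
    cur <- if (full >= 6L) 2.5 else rate_per_month[full + 1L]
    yrs + frac * cur
  }
  vapply(age_months, one, 1)
}

#' Purinergic behavioral response scale (PBRS) total
#'
#' Six items — cage-center avoidance, decreased locomotion,
#' imbalance/ataxia, piloerection, rapid shallow breathing, shivering —
#' each scored 0 (absent), 1 (present) or 2 (present and severe). The
#' total ranges 0 (normal) to 12.
#'
#' @param items integer vector of exactly six scores in `{0, 1, 2}`.
#' @return integer total.
#' @examples
#' pbrs_total(c(2, 2, 2, 2, 1, 1)) # 10
#' @export
pbrs_total <- function(items) {
  if (length(items) != 6L)
    stop_field("items", "exactly six item scores required")
  if (!is.numeric(items) || anyNA(items) ||
      !all(items %in% c(0, 1, 2)))
    stop_field("items", "each item must be 0, 1 or 2")
  as.integer(sum(items))
}

#' Dose-response slopes per sex with a slope-difference test
#'
#' Ordinary least squares of response (temperature at 15 min, or PBRS)
#' on dose, fitted separately per sex for the slope estimates, with the
#' male/female slope difference tested by the sex-by-dose interaction term
#' of the pooled model: F with (1, N-4) degrees of freedom.
#'
#' @param table data.frame with columns `sex`, `dose` (umol/g) and
#'   `response`.
#' @return object of class `dose_response_fit`: `slopes` data.frame (sex,
#'   beta, se, ci_lo, ci_hi, n), `interaction_F`, `interaction_df`,
#'   `interaction_p`.
#' @export
fit_dose_response <- function(table) {
  need <- c("sex", "dose", "response")
  if (!all(need %in% names(table)))
    stop_field("table", paste("needs columns:", paste(need, collapse = ", ")))
  if (any(table$dose < 0)) stop_field("dose", "must be >= 0")
  sexes <- sort(unique(as.character(table$sex)))
  if (length(sexes) != 2L) stop_field("sex", "exactly two sexes expected")
  for (s in sexes)
    if (length(unique(table$dose[table$sex == s])) < 3L)
      stop_field("dose", sprintf("sex '%s' needs >= 3 distinct doses", s))
  slopes <- do.call(rbind, lapply(sexes, function(s) {
    d <- table[table$sex == s, , drop = FALSE]
    f <- lm(response ~ dose, data = d)
    sm <- summary(f)$coefficients
    se <- sm["dose", "Std. Error"]
    beta <- sm["dose", "Estimate"]
    tcrit <- qt(0.975, df = f$df.residual)
    data.frame(sex = s, beta = beta, se = se,
               ci_lo = beta - tcrit * se, ci_hi = beta + tcrit * se,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  pooled <- lm(response ~ dose * sex, data = table)
  av <- anova(pooled)
  Fint <- av["dose:sex", "F value"]
  pint <- av["dose:sex", "Pr(>F)"]
  dfint <- c(1L, pooled$df.residual)
  structure(list(slopes = slopes, interaction_F = Fint,
                 interaction_df = dfint, interaction_p = pint),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  for (i in seq_len(nrow(x$slopes)))
    cat(sprintf("  %s: beta = %.3f +/- %.3f (95%% CI %.3f..%.3f, n = %d)\n",
                x$slopes$sex[i], x$slopes$beta[i], x$slopes$se[i],
                x$slopes$ci_lo[i], x$slopes$ci_hi[i], x$slopes$n[i]))
  cat(sprintf("  slope difference: F(%d,%d) = %.2f, p = %.3g\n",
              x$interaction_df[1L], x$interaction_df[2L],
              x$interaction_F, x$interaction_p))
  invisible(x)
}

#' Phase-window summaries of longitudinal temperature series
#'
#' Replaces mixed-model longitudinal analysis with defined day-window
#' comparisons: for each group and named window, the mean +/- SD of all
#' observations in the window, the delta versus that group's baseline
#' window, and a Welch two-sample p-value (window vs baseline
#' observations).
#'
#' @param series data.frame with columns `animal`, `group`, `day`,
#'   `temperature`.
#' @param windows named list of `c(first_day, last_day)` day ranges; must
#'   include the baseline window.
#' @param baseline name of the baseline window (default `"baseline"`).
#' @return data.frame: `group`, `window`, `n_obs`, `mean`, `sd`, `delta`,
#'   `p_vs_baseline`.
#' @export
phase_summary <- function(series, windows, baseline = "baseline") {
  need <- c("animal", "group", "day", "temperature")
  if (!all(need %in% names(series)))
    stop_field("series", paste("needs columns:", paste(need, collapse = ", ")))
  if (!baseline %in% names(windows))
    stop_field("windows", sprintf("baseline window '%s' missing", baseline))
  pick <- function(d, w) d$temperature[d$day >= w[1L] & d$day <= w[2L]]
  out <- list()
  for (g in sort(unique(as.character(series$group)))) {
    d <- series[series$group == g, , drop = FALSE]
    base <- pick(d, windows[[baseline]])
    if (length(base) == 0L)
      stop_field("windows", sprintf("empty baseline window for group '%s'", g))
    for (w in names(windows)) {
      v <- pick(d, windows[[w]])
      if (length(v) == 0L)
        stop_field("windows", sprintf("window '%s' empty for group '%s'", w, g))
      pv <- if (w == baseline) NA_real_
            else if (sd(v) == 0 && sd(base) == 0)  # degenerate: no variance
              ifelse(mean(v) == mean(base), 1, 0)
            else t.test(v, base)$p.value
      out[[length(out) + 1L]] <- data.frame(
        group = g, window = w, n_obs = length(v),
        mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
        delta = mean(v) - mean(base), p_vs_baseline = pv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
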