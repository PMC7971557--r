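#' Mann-Whitney U test for two groups
#'
#' Rank-sum test with midrank handling of ties. The p-value is exact (full
#' enumeration) when the combined sample size is at most 16 and there are
#' no ties; otherwise the tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `U` (statistic for `x` relative to `y`) and
#'   `p` (two-sided).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L || anyNA(c(x, y)))
    stop_field("x/y", "each group needs >= 2 non-missing values")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 16L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = unname(wt$p.value), exact = exact)
}

#' One-way ANOVA with protected Fisher-LSD post hoc comparisons
#'
#' Omnibus one-way ANOVA with (k-1, N-k) degrees of freedom, followed by
#' pairwise least-significant-difference t-tests that share the pooled
#' within-group mean square. The LSD is "protected": pairwise p-values are
#' reported only when the omnibus p is below `alpha` (otherwise NA).
#'
#' @param groups list of >= 3 numeric vectors, each with >= 2 values.
#' @param alpha omnibus gate for reporting LSD p-values (default 0.05).
#' @return list with `F`, `p`, `df`, and `lsd_p` (symmetric matrix).
#' @export
anova_fisher_lsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stop_field("groups", "needs >= 3 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_field("groups", "every group needs >= 2 values")
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  means <- vapply(groups, mean, 1)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1L; df2 <- N - k
  mse <- ssw / df2
  if (ssw == 0 && ssb == 0) {
    Fstat <- 0; pval <- 1
  } else {
    Fstat <- (ssb / df1) / mse
    pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  lsd <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  if (is.finite(pval) && pval < alpha && mse > 0) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
      tij <- (means[i] - means[j]) / se
      lsd[i, j] <- lsd[j, i] <- 2 * pt(abs(tij), df2, lower.tail = FALSE)
    }
  }
  list(F = Fstat, p = pval, df = c(df1, df2), lsd_p = lsd)
}

#' Benjamini-Hochberg adjusted p-values (FDR)
#'
#' Step-up adjustment with enforced monotonicity, capped at 1.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted values in input order.
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.03, 0.04)) # 0.02 0.02 0.04 0.04
#' @export
bh_fdr <- function(pvals) {
  check_probs(pvals, "pvals")
  p.adjust(pvals, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the tail of the p-value
#' distribution over a lambda grid — `pi0(l) = #\{p > l\} / (m (1 - l))` —
#' smoothed with a natural cubic spline and evaluated at the largest
#' lambda, then converts BH-style step-up quantities into q-values
#' `q_i = min_{t >= p_i} pi0 m t / #\{p <= t\}`, monotone in p. With fewer
#' than 20 p-values pi0 estimation is unstable and falls back to 1 (with a
#' warning), in which case q equals the BH adjusted value.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param lambda_grid grid for pi0 estimation (default 0.05..0.95).
#' @param pi0 optionally force pi0 (e.g. 1), skipping estimation.
#' @return list with `q` (same order as input) and `pi0`.
#' @export
storey_q <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05),
                     pi0 = NULL) {
  check_probs(pvals, "pvals")
  m <- length(pvals)
  if (is.null(pi0)) {
    if (m < 20L) {
      warning("fewer than 20 p-values; falling back to pi0 = 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda_grid,
                      function(l) mean(pvals > l) / (1 - l), 1)
      fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda_grid))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    check_number(pi0, "pi0", lower = 0, upper = 1, allow_zero = FALSE)
  }
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * pvals[o] / rank(pvals, ties.method = "max")[o]
  q <- pmin(1, cummin(q))[ro]
  list(q = q, pi0 = pi0)
}

#' Per-metabolite univariate statistics against the control group
#'
#' For each metabolite: mean treated z, Mann-Whitney U and p, Welch t p,
#' BH-adjusted FDR and Storey q (both computed on the Welch t p-values,
#' the test named by the downstream significance filter), and direction of
#' change.
#'
#' @param zmat a `zscore_matrix` from [control_zscore()].
#' @param treated_group which group to compare against control; default the
#'   single non-control group.
#' @return data.frame, one row per metabolite: `metabolite`, `pathway`,
#'   `mean_z`, `U`, `U_p`, `t_p`, `fdr`, `q`, `direction`.
#' @export
univariate_stats <- function(zmat, treated_group = NULL) {
  stopifnot(inherits(zmat, "zscore_matrix"))
  grp <- zmat$group
  others <- setdiff(unique(grp), zmat$control_group)
  if (is.null(treated_group)) {
    if (length(others) != 1L)
      stop_field("treated_group",
                 "must be named when more than one non-control group exists")
    treated_group <- others
  }
  zc <- zmat$z[grp == zmat$control_group, , drop = FALSE]
  zt <- zmat$z[grp == treated_group, , drop = FALSE]
  p <- ncol(zmat$z)
  U <- U_p <- t_p <- numeric(p)
  for (j in seq_len(p)) {
    mw <- mann_whitney_u(zt[, j], zc[, j])
    U[j] <- mw$U; U_p[j] <- mw$p
    t_p[j] <- t.test(zt[, j], zc[, j])$p.value   # Welch
  }
  mean_z <- colMeans(zt)
  data.frame(
    metabolite = colnames(zmat$z),
    pathway = if (!is.null(zmat$pathway)) unname(zmat$pathway)
              else NA_character_,
    mean_z = mean_z,
    U = U, U_p = U_p, t_p = t_p,
    fdr = bh_fdr(t_p),
    q = storey_q(t_p)$q,
    direction = ifelse(mean_z > 0, "up", ifelse(mean_z < 0, "down", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the study's three-way significance filter
#'
#' A metabolite is called significantly changed iff `fdr < fdr_max` AND
#' `VIP >= vip_min` AND `t_p < p_max`.
#'
#' @param results data.frame from [univariate_stats()].
#' @param vip per-metabolite VIP scores, in the same metabolite order or
#'   named by metabolite.
#' @param fdr_max,vip_min,p_max thresholds (defaults 0.05, 0.9, 0.05).
#' @return `results` with columns `vip` and `significant` added; attributes
#'   `n_significant` and `fraction` carry the headline counts.
#' @export
significance_filter <- function(results, vip, fdr_max = 0.05,
                                vip_min = 0.9, p_max = 0.05) {
  check_probs(fdr_max, "fdr_max"); check_probs(p_max, "p_max")
  check_number(vip_min, "vip_min", lower = 0)
  if (!is.null(names(vip))) vip <- vip[results$metabolite]
  if (length(vip) != nrow(results) || anyNA(vip))
    stop_field("vip", "need a VIP score for every metabolite")
  results$vip <- unname(vip)
  results$significant <- results$fdr < fdr_max &
    results$vip >= vip_min & results$t_p < p_max
  attr(results, "n_significant") <- sum(results$significant)
  attr(results, "fraction") <- sum(results$significant) / nrow(results)
  results
}
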