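#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS2 model of the (already control-scaled) z matrix against a
#' centered one-hot encoding of the group labels, by NIPALS iteration with
#' predictor deflation after each component. For two groups the centered
#' one-hot response is equivalent to +/-1 coding, and the first weight
#' vector is proportional to `X'y`. No additional autoscaling is applied:
#' control-SD z-scores are already on a common scale.
#'
#' @param z a `zscore_matrix` or a numeric samples-x-variables matrix.
#' @param groups group labels per sample (taken from the `zscore_matrix`
#'   when omitted).
#' @param n_components number of latent components A (default 2).
#' @param tol,max_iter NIPALS convergence control: stop when the weight
#'   vector changes by less than `tol` (default 1e-10) or after `max_iter`
#'   iterations (default 500).
#' @return An object of class `plsda`: weights `W` (columns unit norm),
#'   scores `T`, x-loadings `P`, y-loadings `Q`, per-component explained
#'   response sum of squares `SSY` with total `SSY_total`, explained
#'   response fraction `R2Y`, and per-variable `vip`.
#' @export
plsda_fit <- function(z, groups = NULL, n_components = 2L,
                      tol = 1e-10, max_iter = 500L) {
  if (inherits(z, "zscore_matrix")) {
    groups <- groups %||% unname(z$group)
    z <- z$z
  }
  if (is.null(groups)) stop_field("groups", "required")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop_field("groups", "needs >= 2 groups")
  check_number(n_components, "n_components", lower = 1, integer = TRUE)
  n <- nrow(z); p <- ncol(z)
  if (n < n_components + 2L)
    stop_field("n_components", "needs n >= n_components + 2 samples")
  X <- scale(z, center = TRUE, scale = FALSE)
  if (all(abs(X) < .Machine$double.eps))
    stop_field("z", "constant predictor matrix")
  lev <- sort(unique(groups))
  Y <- scale(outer(groups, lev, `==`) * 1, center = TRUE, scale = FALSE)
  SSY_total <- sum(Y^2)

  A <- n_components
  W <- matrix(0, p, A); Tm <- matrix(0, n, A)
  P <- matrix(0, p, A); Q <- matrix(0, ncol(Y), A)
  SSY <- numeric(A)
  Xa <- X; Ya <- Y
  for (a in seq_len(A)) {
    u <- Ya[, which.max(apply(Ya, 2L, var))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xa, u))
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps)
        stop_field("z", sprintf("degenerate component %d (zero weight)", a))
      w <- w / nw
      tt <- drop(Xa %*% w)
      q <- drop(crossprod(Ya, tt)) / sum(tt^2)
      u <- drop(Ya %*% q) / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    pp <- drop(crossprod(Xa, tt)) / sum(tt^2)
    SSY[a] <- sum(tt^2) * sum(q^2)  # ||t q'||^2: response SS carried by t_a
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pp; Q[, a] <- q
    Xa <- Xa - tcrossprod(tt, pp)
    Ya <- Ya - tcrossprod(tt, q)
  }
  rownames(W) <- rownames(P) <- colnames(z)
  rownames(Tm) <- rownames(z)
  fit <- structure(
    list(W = W, T = Tm, P = P, Q = Q, SSY = SSY, SSY_total = SSY_total,
         R2Y = SSY / SSY_total, n_components = A,
         groups = groups, levels = lev),
    class = "plsda")
  fit$vip <- vip_scores(fit)
  fit
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )` with unit-norm
#' weight vectors and `SS_a` the response sum of squares explained by
#' component a. By construction the mean squared VIP over variables is
#' exactly 1, so VIP >= 1 marks above-average contribution.
#'
#' @param model a fitted [plsda_fit()] object.
#' @return named numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda")) stop_field("model", "must be a plsda fit")
  if (sum(model$SSY) <= 0) stop_field("model", "zero explained response SS")
  p <- nrow(model$W)
  w2 <- model$W^2                       # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% model$SSY) / sum(model$SSY))
  setNames(vip, rownames(model$W))
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d components, %d samples x %d variables\n",
              x$n_components, nrow(x$T), nrow(x$W)))
  cat("groups:", paste(x$levels, collapse = ", "), "\n")
  cat("explained response variance (R2Y):",
      paste(sprintf("%.3f", x$R2Y), collapse = ", "), "\n")
  invisible(x)
}
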