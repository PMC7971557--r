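#' Log2-transform an AUC matrix
#'
#' Metabolomic peak areas span orders of magnitude and are right-skewed;
#' all downstream scoring operates on the log2 scale.
#'
#' @param x a [metabolite_matrix()] or a positive numeric matrix.
#' @return The same structure with AUC values replaced by `log2(AUC)`.
#' @export
log2_transform <- function(x) {
  m <- if (inherits(x, "metabolite_matrix")) x$auc else x
  if (!is.numeric(m)) stop_field("x", "must be numeric")
  if (any(m <= 0)) stop_field("x", "all AUC values must be > 0")
  out <- log2(m)
  if (inherits(x, "metabolite_matrix")) {
    x$auc <- out
    attr(x, "scale") <- "log2"
    x
  } else out
}

#' Generalized log2 transform for concentration data
#'
#' `glog2(y) = log2(y + 1)`, defined at zero and well behaved for
#' fractional concentrations between 0 and 1 (e.g. cytokines in pg/ml).
#'
#' @param y numeric vector of non-negative concentrations.
#' @return `log2(y + 1)`.
#' @examples
#' glog2(c(0, 1, 3)) # 0, 1, 2
#' @export
glog2 <- function(y) {
  if (!is.numeric(y) || anyNA(y)) stop_field("y", "must be numeric, no NA")
  if (any(y < 0)) stop_field("y", "must be >= 0")
  log2(y + 1)
}

#' Control-referenced z-scores on the log2 scale
#'
#' Standardizes each metabolite against the control group's mean and sample
#' standard deviation (denominator n-1) of the log2 AUCs, so every effect
#' size is expressed in control-SD units. Metabolites whose control SD is
#' zero cannot be scaled and are dropped with a warning.
#'
#' @param log2_matrix a [metabolite_matrix()] already log2-transformed (see
#'   [log2_transform()]), or a numeric log2-scale matrix plus `group`.
#' @param control_group the group label of the reference (control) arm.
#' @param group group labels, required only when `log2_matrix` is a bare
#'   matrix.
#' @return An object of class `zscore_matrix`: list with elements `z`
#'   (samples x metabolites), `mu_ctrl`, `sd_ctrl`, `group`,
#'   `control_group`, `pathway` (if available) and `dropped`.
#' @export
control_zscore <- function(log2_matrix, control_group, group = NULL) {
  if (inherits(log2_matrix, "metabolite_matrix")) {
    if (!identical(attr(log2_matrix, "scale"), "log2"))
      log2_matrix <- log2_transform(log2_matrix)
    m <- log2_matrix$auc
    group <- log2_matrix$group
    pathway <- log2_matrix$pathway
    sex <- log2_matrix$sex
  } else {
    m <- log2_matrix
    if (is.null(group)) stop_field("group", "required for a bare matrix")
    pathway <- NULL
    sex <- NULL
  }
  if (!control_group %in% group)
    stop_field("control_group",
               sprintf("group '%s' not present in data", control_group))
  ctrl <- m[group == control_group, , drop = FALSE]
  if (nrow(ctrl) < 3L)
    stop_field("control_group", "needs at least 3 control samples")
  mu <- colMeans(ctrl)
  sdev <- apply(ctrl, 2L, sd)
  keep <- sdev > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d metabolite(s) with zero control SD: %s",
                    sum(!keep),
                    paste(colnames(m)[!keep], collapse = ", ")))
  }
  z <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep], "-"),
             2L, sdev[keep], "/")
  structure(
    list(z = z, mu_ctrl = mu[keep], sd_ctrl = sdev[keep],
         group = setNames(as.character(group), rownames(m)),
         control_group = control_group,
         pathway = if (!is.null(pathway)) pathway[keep] else NULL,
         sex = sex,
         dropped = colnames(m)[!keep]),
    class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf(
    "<zscore_matrix> %d samples x %d metabolites (control = '%s'%s)\n",
    nrow(x$z), ncol(x$z), x$control_group,
    if (length(x$dropped)) sprintf(", %d dropped", length(x$dropped)) else ""))
  invisible(x)
}

# per-metabolite mean z over the non-control (or named) group
mean_treated_z <- function(zmat, treated_group = NULL) {
  stopifnot(inherits(zmat, "zscore_matrix"))
  idx <- if (is.null(treated_group)) zmat$group != zmat$control_group
         else zmat$group == treated_group
  colMeans(zmat$z[idx, , drop = FALSE])
}
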