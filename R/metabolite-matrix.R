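#' Construct a sample-by-metabolite AUC matrix
#'
#' The central metabolomics container: positive chromatographic peak areas
#' (AUC, arbitrary units) for each sample and metabolite, a treatment group
#' label per sample, an optional sex label, and a biochemical-pathway
#' assignment per metabolite.
#'
#' @param auc numeric matrix, samples in rows, metabolites in columns, all
#'   values strictly positive; dimnames give sample and metabolite ids.
#' @param group character vector of group labels, one per sample.
#' @param pathway named character vector mapping every metabolite to exactly
#'   one pathway.
#' @param sex optional character vector per sample.
#' @return An object of class `metabolite_matrix`.
#' @examples
#' m <- metabolite_matrix(
#'   auc = matrix(2^rnorm(12, 15), 4, 3,
#'                dimnames = list(paste0("s", 1:4), paste0("met", 1:3))),
#'   group = c("saline", "saline", "ATP", "ATP"),
#'   pathway = c(met1 = "Purines", met2 = "Purines", met3 = "Amino acids"))
#' m
#' @export
metabolite_matrix <- function(auc, group, pathway, sex = NULL) {
  if (!is.matrix(auc) || !is.numeric(auc))
    stop_field("auc", "must be a numeric matrix (samples x metabolites)")
  if (is.null(rownames(auc)) || is.null(colnames(auc)))
    stop_field("auc", "must have sample rownames and metabolite colnames")
  if (anyDuplicated(rownames(auc)))
    stop_field("auc", "duplicate sample ids")
  if (anyDuplicated(colnames(auc)))
    stop_field("auc", "duplicate metabolite ids")
  if (anyNA(auc))
    stop_field("auc", "missing values are not allowed (no imputation path)")
  if (any(auc <= 0)) {
    bad <- which(auc <= 0, arr.ind = TRUE)[1L, ]
    stop_field("auc", sprintf(
      "non-positive AUC for sample '%s', metabolite '%s'",
      rownames(auc)[bad[1L]], colnames(auc)[bad[2L]]))
  }
  group <- as.character(group)
  if (length(group) != nrow(auc) || anyNA(group) || any(!nzchar(group)))
    stop_field("group", "every sample needs a non-empty group label")
  pathway <- unlist(pathway)
  if (is.null(names(pathway)) ||
      !all(colnames(auc) %in% names(pathway)))
    stop_field("pathway", "every metabolite needs a named pathway entry")
  pathway <- pathway[colnames(auc)]
  if (!is.null(sex)) {
    sex <- as.character(sex)
    if (length(sex) != nrow(auc))
      stop_field("sex", "must have one entry per sample")
  }
  structure(
    list(auc = auc, group = setNames(group, rownames(auc)),
         pathway = pathway, sex = sex),
    class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d metabolites, %d pathways\n",
              nrow(x$auc), ncol(x$auc), length(unique(x$pathway))))
  tab <- table(x$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$auc)

metabolite_names <- function(x) colnames(x$auc)
sample_names <- function(x) rownames(x$auc)
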