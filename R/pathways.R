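#' Pathway impact ranking by summed VIP
#'
#' Significant metabolites are grouped into their biochemical pathways and
#' the member VIP scores are summed; pathways are ranked by that sum
#' (descending), with ties broken by significant-member count and then by
#' pathway name, so the ranking is deterministic.
#'
#' @param results data.frame from [significance_filter()] (needs columns
#'   `metabolite`, `pathway`, `mean_z`, `vip`, `significant`).
#' @return data.frame: `pathway`, `n_members`, `n_significant`, `vip_sum`,
#'   `direction`, `rank`, sorted by rank. Empty if nothing is significant.
#' @export
aggregate_pathway_vip <- function(results) {
  need <- c("metabolite", "pathway", "mean_z", "vip", "significant")
  if (!all(need %in% names(results)))
    stop_field("results", paste("needs columns:", paste(need, collapse = ", ")))
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(pathway = character(), n_members = integer(),
                      n_significant = integer(), vip_sum = numeric(),
                      direction = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  n_members <- table(results$pathway)
  agg <- do.call(rbind, lapply(split(sig, sig$pathway), function(d) {
    data.frame(pathway = d$pathway[1L],
               n_members = as.integer(n_members[[d$pathway[1L]]]),
               n_significant = nrow(d),
               vip_sum = sum(d$vip),
               direction = classify_pathway_direction(d$mean_z),
               stringsAsFactors = FALSE)
  }))
  o <- order(-agg$vip_sum, -agg$n_significant, agg$pathway)
  agg <- agg[o, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Classify a pathway's direction of change
#'
#' `"increased"` if all significant members moved up, `"decreased"` if all
#' moved down, `"mixed"` otherwise. Invariant to member ordering.
#'
#' @param mean_z mean treated z of the pathway's significant members.
#' @return one of `"increased"`, `"decreased"`, `"mixed"`.
#' @export
classify_pathway_direction <- function(mean_z) {
  if (length(mean_z) < 1L) stop_field("mean_z", "needs >= 1 member")
  if (all(mean_z > 0)) "increased"
  else if (all(mean_z < 0)) "decreased"
  else "mixed"
}

#' Count changed metabolites
#'
#' @param count number significantly changed.
#' @param total number measured.
#' @return list with `count`, `total`, `percent` (rounded to the nearest
#'   integer, e.g. 202 of 401 -> 50).
#' @export
count_changed <- function(count, total) {
  check_number(count, "count", lower = 0, integer = TRUE)
  check_number(total, "total", lower = count, integer = TRUE)
  list(count = as.integer(count), total = as.integer(total),
       percent = as.integer(round(100 * count / total)))
}
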