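# Delimited-text I/O. CSV vs TSV is auto-detected from the file extension
# (.csv -> comma, anything else -> tab). Samples are rows by convention; a
# transpose flag handles metabolites-as-rows tables.

read_delim_auto <- function(path, row_names = FALSE) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
           row.names = if (row_names) 1L else NULL)
}

write_delim_auto <- function(df, path, row_names = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = row_names,
              col.names = TRUE)
  invisible(path)
}

#' Read a sample-by-metabolite AUC table with a pathway map
#'
#' The main table has samples as rows: a sample-id column (first), the
#' group column, optionally a `sex` column, and one numeric column per
#' metabolite. The pathway map is a two-column table (metabolite, pathway).
#' Metabolites absent from the map are assigned pathway `"Unmapped"` with a
#' warning. Non-numeric or non-positive AUC cells are an error naming the
#' offending sample and metabolite.
#'
#' @param path CSV/TSV of AUC values.
#' @param pathway_map_path CSV/TSV mapping metabolite to pathway.
#' @param group_column name of the group-label column (default "group").
#' @param transpose set TRUE when metabolites are rows in the file.
#' @return a [metabolite_matrix()].
#' @export
read_metabolite_table <- function(path, pathway_map_path,
                                  group_column = "group",
                                  transpose = FALSE) {
  df <- read_delim_auto(path)
  if (transpose) {
    ids <- df[[1L]]
    df <- as.data.frame(t(df[-1L]))
    names(df) <- ids
    df <- cbind(sample = rownames(df), df)
  }
  sample_ids <- as.character(df[[1L]])
  df <- df[-1L]
  if (!group_column %in% names(df))
    stop_field("group_column",
               sprintf("column '%s' not found in %s", group_column, path))
  group <- as.character(df[[group_column]])
  sex <- if ("sex" %in% names(df)) as.character(df[["sex"]]) else NULL
  met_cols <- setdiff(names(df), c(group_column, "sex"))
  auc <- matrix(NA_real_, length(sample_ids), length(met_cols),
                dimnames = list(sample_ids, met_cols))
  for (mc in met_cols) {
    v <- suppressWarnings(as.numeric(df[[mc]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad))
      stop_field("auc", sprintf(
        "non-numeric or non-positive AUC for sample '%s', metabolite '%s'",
        sample_ids[bad[1L]], mc))
    auc[, mc] <- v
  }
  map <- read_delim_auto(pathway_map_path)
  pathway <- setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  missing <- setdiff(met_cols, names(pathway))
  if (length(missing)) {
    warning(sprintf("%d metabolite(s) absent from pathway map assigned 'Unmapped'",
                    length(missing)))
    pathway[missing] <- "Unmapped"
  }
  metabolite_matrix(auc, group, pathway[met_cols], sex = sex)
}

#' Write a metabolite matrix (and its pathway map) to delimited text
#'
#' Writes the sample-by-metabolite table in the exact layout
#' [read_metabolite_table()] accepts, so synthetic runs exercise the full
#' I/O path. AUCs are written at full precision (`format(..., digits =
#' 15)`), so a read/write round trip is the identity to float tolerance.
#'
#' @param m a [metabolite_matrix()].
#' @param path output CSV/TSV for the AUC table.
#' @param pathway_map_path optional output for the metabolite-pathway map.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(m, path, pathway_map_path = NULL) {
  stopifnot(inherits(m, "metabolite_matrix"))
  df <- data.frame(sample = rownames(m$auc), group = unname(m$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(m$sex)) df$sex <- m$sex
  auc <- as.data.frame(apply(m$auc, 2L, format, digits = 15, trim = TRUE),
                       check.names = FALSE)
  df <- cbind(df, auc)
  write_delim_auto(df, path)
  if (!is.null(pathway_map_path))
    write_delim_auto(data.frame(metabolite = names(m$pathway),
                                pathway = unname(m$pathway)),
                     pathway_map_path)
  invisible(path)
}

#' Read interval-level calorimetry traces
#'
#' Expects columns `animal`, `group`, `start_min`, `vo2`, `vco2`,
#' `beam_breaks` (one row per 13-minute interval). Rows are sorted by time
#' within animal; duplicate interval times for an animal are an error.
#'
#' @param path CSV/TSV file.
#' @return validated, sorted data.frame of intervals.
#' @export
read_calorimetry <- function(path) {
  validate_calorimetry(read_delim_auto(path))
}

#' Read a breath-canister measurement table
#'
#' Columns `animal`, `group`, `timepoint_min`, `is_background`, then one
#' numeric column per species (must include `CO2`). Mixing ratios must be
#' non-negative.
#'
#' @param path CSV/TSV file.
#' @return data.frame in the layout [background_subtract()] accepts.
#' @export
read_breath_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("animal", "group", "timepoint_min", "is_background")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("path", paste("missing column(s):", paste(miss, collapse = ", ")))
  df$is_background <- as.logical(df$is_background)
  sp <- breath_species(df)
  if (!"CO2" %in% sp) stop_field("path", "missing CO2 column")
  for (s in sp) {
    if (!is.numeric(df[[s]]) || anyNA(df[[s]]) || any(df[[s]] < 0))
      stop_field("path", sprintf("column '%s' must be numeric and >= 0", s))
  }
  df
}
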