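#' Simulate breath-canister VOC tables
#'
#' Emulates the breathomics design: each animal contributes canister
#' samples at 1, 5 and 10 minutes post-injection, plus room-air background
#' samples collected before and after the study. A sample's mixing ratio is
#' `background + minute_volume * excess`, where the per-animal
#' minute-volume factor (lognormal) scales every exhaled species —
#' including CO2 — by the same amount, reproducing the confound that CO2
#' normalization removes. Treated animals multiply the exhaled excess of
#' selected species by `effect` from `effects`.
#'
#' @param background named vector of room-air mixing ratios (ppb; CO2 in
#'   ppm). Must include `"CO2"`.
#' @param excess named vector of exhaled excess above background for an
#'   untreated animal at unit minute volume (same units).
#' @param effects named vector of multiplicative treatment effects on the
#'   excess (e.g. `c(CO = 2)`); species not named are unaffected.
#' @param n_per_group animals per group (saline / ATP).
#' @param minute_volume_sdlog SD of the log minute-volume factor
#'   (default 0.2).
#' @param noise_cv measurement coefficient of variation (default 0.05).
#' @param n_background number of room-air samples (default 2).
#' @param seed integer seed.
#' @return data.frame with `animal`, `group`, `timepoint_min`,
#'   `is_background`, and one column per species.
#' @export
simulate_breath <- function(background, excess, effects = numeric(),
                            n_per_group = 3L, minute_volume_sdlog = 0.2,
                            noise_cv = 0.05, n_background = 2L, seed = 1L) {
  if (is.null(names(background)) || is.null(names(excess)))
    stop_field("background/excess", "must be named by species")
  if (!"CO2" %in% names(background))
    stop_field("background", "must include CO2")
  if (any(background < 0)) stop_field("background", "must be >= 0")
  if (any(excess < 0)) stop_field("excess", "must be >= 0")
  if (!all(names(excess) %in% names(background)))
    stop_field("excess", "species missing from background")
  check_number(n_per_group, "n_per_group", lower = 1, integer = TRUE)
  species <- names(background)
  exc <- setNames(rep(0, length(species)), species)
  exc[names(excess)] <- excess
  tps <- c(1, 5, 10)
  rows <- list()
  with_seed(seed, {
    for (b in seq_len(n_background)) {
      meas <- background * (1 + rnorm(length(species), 0, noise_cv))
      rows[[length(rows) + 1L]] <- c(list(animal = NA_character_,
                                          group = "room_air",
                                          timepoint_min = NA_real_,
                                          is_background = TRUE),
                                     as.list(pmax(meas, 0)))
    }
    for (grp in c("saline", "ATP")) {
      mult <- setNames(rep(1, length(species)), species)
      if (grp == "ATP" && length(effects)) {
        if (is.null(names(effects)))
          stop_field("effects", "must be named by species")
        mult[names(effects)] <- effects
      }
      for (ai in seq_len(n_per_group)) {
        mv <- exp(rnorm(1, 0, minute_volume_sdlog))
        for (tp in tps) {
          true <- background + mv * mult * exc
          meas <- true * (1 + rnorm(length(species), 0, noise_cv))
          rows[[length(rows) + 1L]] <- c(
            list(animal = sprintf("%s_%02d", grp, ai), group = grp,
                 timepoint_min = tp, is_background = FALSE),
            as.list(pmax(meas, 0)))
        }
      }
    }
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

breath_species <- function(samples) {
  setdiff(names(samples), c("animal", "group", "timepoint_min", "is_background"))
}

#' Subtract room-air background from breath samples
#'
#' The background is the mean over room-air samples, per species. Excess
#' values below zero are physically impossible and are clipped to 0; the
#' number of clipped cells is reported in a warning and as an attribute.
#'
#' @param samples data.frame from [simulate_breath()] or
#'   [read_breath_table()]; room-air rows flagged by `is_background`.
#' @param signed keep negative excess values instead of clipping
#'   (default FALSE).
#' @return the animal rows with species columns replaced by excess mixing
#'   ratios; attribute `n_clipped` counts clipped cells.
#' @export
background_subtract <- function(samples, signed = FALSE) {
  sp <- breath_species(samples)
  bg_rows <- samples[samples$is_background, sp, drop = FALSE]
  if (nrow(bg_rows) < 1L)
    stop_field("samples", "needs >= 1 room-air background sample")
  if (anyNA(bg_rows))
    stop_field("samples", "species missing in a background sample")
  bg <- colMeans(bg_rows)
  out <- samples[!samples$is_background, , drop = FALSE]
  ex <- sweep(as.matrix(out[sp]), 2L, bg, "-")
  n_clipped <- 0L
  if (!signed) {
    n_clipped <- sum(ex < 0)
    if (n_clipped > 0L)
      warning(sprintf("%d excess value(s) below background clipped to 0",
                      n_clipped))
    ex <- pmax(ex, 0)
  }
  out[sp] <- ex
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Normalize exhaled species by CO2 production
#'
#' Exhaled mixing ratios scale with minute volume; dividing each species'
#' excess by the same sample's CO2 excess (ppb per ppm CO2) removes that
#' multiplicative confound exactly. Samples with zero CO2 excess cannot be
#' normalized and are excluded with a warning.
#'
#' @param excess data.frame from [background_subtract()].
#' @return the same rows (minus excluded ones) with every species column
#'   except CO2 divided by the CO2 excess; CO2 column retained unscaled.
#' @export
normalize_by_co2 <- function(excess) {
  sp <- breath_species(excess)
  if (!"CO2" %in% sp) stop_field("excess", "needs a CO2 column")
  co2 <- excess$CO2
  bad <- !(co2 > 0)
  if (any(bad)) {
    warning(sprintf("excluding %d sample(s) with zero CO2 excess", sum(bad)))
    excess <- excess[!bad, , drop = FALSE]
    co2 <- co2[!bad]
  }
  for (s in setdiff(sp, "CO2")) excess[[s]] <- excess[[s]] / co2
  excess
}

#' Pool timepoints and compare groups per species
#'
#' Each animal's three timepoint samples are averaged, then groups are
#' compared per species with Welch's t-test, BH-corrected across species.
#'
#' @param normalized data.frame from [normalize_by_co2()].
#' @param group_a,group_b the two groups to compare (defaults: the two
#'   groups present, alphabetical).
#' @return data.frame per species: group means +/- SD, `p`, `fdr`.
#' @export
pool_and_compare <- function(normalized, group_a = NULL, group_b = NULL) {
  sp <- setdiff(breath_species(normalized), "CO2")
  groups <- sort(unique(normalized$group))
  group_a <- group_a %||% groups[1L]
  group_b <- group_b %||% groups[2L]
  per_animal <- aggregate(normalized[sp],
                          by = list(animal = normalized$animal,
                                    group = normalized$group), FUN = mean)
  if (anyNA(per_animal[sp]))
    stop_field("normalized", "species missing for an animal")
  a <- per_animal[per_animal$group == group_a, sp, drop = FALSE]
  b <- per_animal[per_animal$group == group_b, sp, drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop_field("normalized", "needs >= 2 animals per group")
  res <- do.call(rbind, lapply(sp, function(s) {
    pv <- if (sd(a[[s]]) == 0 && sd(b[[s]]) == 0)
      ifelse(mean(a[[s]]) == mean(b[[s]]), 1, 0)
    else t.test(b[[s]], a[[s]])$p.value
    data.frame(species = s,
               mean_a = mean(a[[s]]), sd_a = sd(a[[s]]),
               mean_b = mean(b[[s]]), sd_b = sd(b[[s]]),
               p = pv, stringsAsFactors = FALSE)
  }))
  names(res)[2:5] <- c(paste0("mean_", group_a), paste0("sd_", group_a),
                       paste0("mean_", group_b), paste0("sd_", group_b))
  res$fdr <- bh_fdr(res$p)
  res
}
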