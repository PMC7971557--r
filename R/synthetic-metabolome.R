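#' Specify a synthetic targeted-metabolomics experiment
#'
#' Describes a two-group (control vs treated) plasma metabolomics design on
#' which the whole pipeline can be exercised. AUCs are lognormal: normal on
#' the log2 scale around per-metabolite control means, matching the
#' log2-transform-then-z analysis convention. Treatment shifts each
#' metabolite by `effect_z` control-SDs on the log2 scale; metabolites that
#' share a supercluster additionally load on a common latent factor so that
#' coordinated change is genuine correlation, not merely equal means.
#'
#' @param metabolites data.frame with columns `name`, `pathway`, `effect_z`
#'   (shift in control-SD units) and optionally `supercluster` (integer or
#'   NA for none).
#' @param n_control,n_treated samples per arm (each >= 3).
#' @param control_log2_mean,control_log2_sd per-metabolite control mean and
#'   SD of log2(AUC); recycled if scalar. SD must be > 0.
#' @param latent_loading loading of superclustered metabolites on their
#'   shared latent factor, in control-SD units per latent SD.
#' @param seed integer seed; the generator uses one private RNG stream.
#' @return An object of class `metabolome_spec`.
#' @seealso [simulate_metabolome()], [hyperpurinergia_spec()]
#' @export
metabolome_spec <- function(metabolites, n_control = 8L, n_treated = 8L,
                            control_log2_mean = 18, control_log2_sd = 0.5,
                            latent_loading = 0.5, seed = 1L) {
  if (!is.data.frame(metabolites) ||
      !all(c("name", "pathway", "effect_z") %in% names(metabolites)))
    stop_field("metabolites",
               "needs columns 'name', 'pathway', 'effect_z'")
  p <- nrow(metabolites)
  if (p < 1L) stop_field("metabolites", "at least one metabolite required")
  if (anyDuplicated(metabolites$name))
    stop_field("metabolites", "duplicate metabolite names")
  if (anyNA(metabolites$pathway) || any(!nzchar(metabolites$pathway)))
    stop_field("metabolites", "every metabolite needs exactly one pathway")
  if (!is.numeric(metabolites$effect_z) || !all(is.finite(metabolites$effect_z)))
    stop_field("effect_z", "must be finite numeric")
  check_number(n_control, "n_control", lower = 3, integer = TRUE)
  check_number(n_treated, "n_treated", lower = 3, integer = TRUE)
  control_log2_mean <- rep_len(control_log2_mean, p)
  control_log2_sd <- rep_len(control_log2_sd, p)
  if (any(!is.finite(control_log2_sd)) || any(control_log2_sd <= 0))
    stop_field("control_log2_sd", "must be > 0")
  if (is.null(metabolites$supercluster))
    metabolites$supercluster <- NA_integer_
  check_number(latent_loading, "latent_loading")
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(metabolites = metabolites,
         n_control = as.integer(n_control),
         n_treated = as.integer(n_treated),
         control_log2_mean = control_log2_mean,
         control_log2_sd = control_log2_sd,
         latent_loading = latent_loading,
         seed = as.integer(seed)),
    class = "metabolome_spec")
}

#' Default spec emulating the acute (30-minute) eATP plasma response
#'
#' Builds a [metabolome_spec()] with the dimensions and effect scales of the
#' acute hyperpurinergia study: 401 measurable metabolites in 37 biochemical
#' pathways, n = 8 per arm, and two coordinated superclusters — 63
#' metabolites decreased (mean z -3.4, SD 2.0; containing all 19 amino
#' acids at mean -5.0, SD 2.6) and 71 increased (mean z +3.2, SD 1.8;
#' containing 11 microbiome products at mean +3.5, SD 1.5). The remaining
#' 267 metabolites are null. Effect sizes are laid out deterministically as
#' evenly spaced normal quantiles so the stated means hold exactly.
#'
#' @param n_metabolites,n_pathways,n_control,n_treated study dimensions.
#' @param seed integer seed passed to the spec.
#' @return A `metabolome_spec`.
#' @export
hyperpurinergia_spec <- function(n_metabolites = 401L, n_pathways = 37L,
                                 n_control = 8L, n_treated = 8L, seed = 1L) {
  check_number(n_metabolites, "n_metabolites", lower = 150, integer = TRUE)
  check_number(n_pathways, "n_pathways", lower = 4, integer = TRUE)
  n_aa <- 19L; n_dec_other <- 44L   # decreased cluster: 63 total
  n_micro <- 11L; n_inc_other <- 60L # increased cluster: 71 total
  n_planted <- n_aa + n_dec_other + n_micro + n_inc_other
  n_null <- n_metabolites - n_planted

  # nested effect layout keeps both the subgroup and whole-cluster means:
  # 19 AA at -5.0 => other 44 decreased at (63*-3.4 - 19*-5.0)/44
  dec_other_mean <- (63 * -3.4 - n_aa * -5.0) / n_dec_other
  inc_other_mean <- (71 * 3.2 - n_micro * 3.5) / n_inc_other
  effects <- c(
    spread_normal(n_aa, -5.0, 2.6),
    spread_normal(n_dec_other, dec_other_mean, 1.4),
    spread_normal(n_micro, 3.5, 1.5),
    spread_normal(n_inc_other, inc_other_mean, 1.4),
    rep(0, n_null))
  cluster <- c(rep(1L, n_aa + n_dec_other),
               rep(2L, n_micro + n_inc_other),
               rep(NA_integer_, n_null))

  pathways <- c("Amino acids", "Microbiome metabolites",
                sprintf("Pathway %02d", seq_len(n_pathways - 2L)))
  pw <- c(rep("Amino acids", n_aa),
          rep(pathways[2 + (seq_len(n_dec_other) %% (n_pathways - 2L))],
              length.out = n_dec_other),
          rep("Microbiome metabolites", n_micro),
          rep(pathways[2 + (seq_len(n_inc_other) %% (n_pathways - 2L))],
              length.out = n_inc_other),
          rep(pathways[-(1:2)], length.out = n_null))

  mets <- data.frame(
    name = sprintf("met%03d", seq_len(n_metabolites)),
    pathway = pw,
    effect_z = effects,
    supercluster = cluster,
    stringsAsFactors = FALSE)
  metabolome_spec(
    mets, n_control = n_control, n_treated = n_treated,
    control_log2_mean = seq(12, 28, length.out = n_metabolites),
    control_log2_sd = 0.5, latent_loading = 0.5, seed = seed)
}

#' Simulate a metabolite AUC table from a spec
#'
#' Control samples draw `log2(AUC) ~ N(mu_j, sd_j)`; treated samples draw
#' around `mu_j + effect_z_j * sd_j`, plus, for superclustered metabolites,
#' `loading * sd_j * f_c` where `f_c ~ N(0, 1)` is one latent factor per
#' cluster per treated sample. AUCs are `2^log2`, so always positive with
#' no missing values. The same seed and spec give bit-identical output.
#'
#' @param spec a [metabolome_spec()].
#' @return A [metabolite_matrix()] with groups `"control"` and `"treated"`.
#' @export
simulate_metabolome <- function(spec) {
  if (!inherits(spec, "metabolome_spec"))
    stop_field("spec", "must be a metabolome_spec")
  p <- nrow(spec$metabolites)
  n_c <- spec$n_control; n_t <- spec$n_treated
  mu <- spec$control_log2_mean; sdv <- spec$control_log2_sd
  eff <- spec$metabolites$effect_z
  cl <- spec$metabolites$supercluster

  with_seed(spec$seed, {
    ctrl <- matrix(rnorm(n_c * p, mean = rep(mu, each = n_c),
                         sd = rep(sdv, each = n_c)), n_c, p)
    trt <- matrix(rnorm(n_t * p,
                        mean = rep(mu + eff * sdv, each = n_t),
                        sd = rep(sdv, each = n_t)), n_t, p)
    clusters <- sort(unique(cl[!is.na(cl)]))
    for (cc in clusters) {
      f <- rnorm(n_t)                       # one latent draw per treated sample
      j <- which(!is.na(cl) & cl == cc)
      trt[, j] <- trt[, j] +
        spec$latent_loading * outer(f, sdv[j])
    }
    log2m <- rbind(ctrl, trt)
  })

  rownames(log2m) <- c(sprintf("ctrl_%02d", seq_len(n_c)),
                       sprintf("trt_%02d", seq_len(n_t)))
  colnames(log2m) <- spec$metabolites$name
  metabolite_matrix(
    auc = 2^log2m,
    group = c(rep("control", n_c), rep("treated", n_t)),
    pathway = setNames(spec$metabolites$pathway, spec$metabolites$name))
}
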