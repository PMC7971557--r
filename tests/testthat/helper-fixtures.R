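# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

# tiny valid AUC matrix (3 samples x 2 metabolites)
tiny_matrix <- function() {
  metabolite_matrix(
    auc = matrix(c(8, 16, 32, 100, 200, 400), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("metA", "metB"))),
    group = c("control", "control", "treated"),
    pathway = c(metA = "Purines", metB = "Amino acids"))
}

# simple two-group z-scored dataset with one planted informative variable
planted_zscores <- function(n_per_group = 8, p = 10, effect = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p,
              dimnames = list(sprintf("s%02d", seq_len(2 * n_per_group)),
                              sprintf("v%02d", seq_len(p))))
  x[(n_per_group + 1):(2 * n_per_group), 1] <-
    x[(n_per_group + 1):(2 * n_per_group), 1] + effect
  list(x = x, groups = rep(c("control", "treated"), each = n_per_group))
}

# exhaustive Mann-Whitney oracle: enumerate all C(n+m, n) group assignments
# of the pooled values and compute the two-sided tail probability of U
mw_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(N, n)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# spec for a metabolome with k planted effects of size `effect` among p
planted_spec <- function(p = 50, k = 19, effect = -5, n = 8, seed = 1,
                         cluster = FALSE) {
  mets <- data.frame(
    name = sprintf("met%03d", seq_len(p)),
    pathway = rep(c("Planted", "Null pathway A", "Null pathway B"),
                  c(k, ceiling((p - k) / 2), floor((p - k) / 2))),
    effect_z = c(rep(effect, k), rep(0, p - k)),
    supercluster = if (cluster) c(rep(1L, k), rep(NA_integer_, p - k))
                   else NA_integer_)
  metabolome_spec(mets, n_control = n, n_treated = n, seed = seed)
}

# 10 latent superclusters of 10 metabolites; clusters 1 and 2 planted with
# strong opposite effects at the study's cluster scales, the rest null
ten_cluster_spec <- function(seed = 1, effect_up = 3.2, effect_dn = -3.4,
                             n = 8) {
  mets <- data.frame(
    name = sprintf("met%03d", 1:100),
    pathway = rep(sprintf("pw%02d", 1:20), each = 5),
    effect_z = c(rep(effect_up, 10), rep(effect_dn, 10), rep(0, 80)),
    supercluster = rep(1:10, each = 10))
  metabolome_spec(mets, n_control = n, n_treated = n, seed = seed)
}
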