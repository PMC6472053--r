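# shared fixtures: fast acquisition settings and small reference profiles

quiet_params <- function(...) {
  acquisition_params(noise_sd = 0, ...)
}

# single-species profiles for stoichiometric limit checks
pure_profile <- function(species) {
  args <- stats::setNames(list(1), species)
  do.call(fa_profile, args)
}

# realistic random milk profiles (mole-fraction ranges of bovine milk fat)
random_milk_profile <- function(u = stats::runif(8)) {
  lo <- c(butyric = 0.08, saturated_pool = 0.55, oleic_pool = 0.15,
          linoleic = 0.010, alpha_linolenic = 0.004, cla_ct = 0.003,
          cla_tt = 0.0005, caproleic = 0.0015)
  hi <- c(butyric = 0.13, saturated_pool = 0.72, oleic_pool = 0.28,
          linoleic = 0.040, alpha_linolenic = 0.015, cla_ct = 0.012,
          cla_tt = 0.003, caproleic = 0.006)
  p <- lo + u * (hi - lo)
  do.call(fa_profile, c(as.list(p), renormalize = TRUE))
}

# true per-chain mole percentages implied by a profile
truth_pct <- function(profile) {
  p <- unclass(profile)
  ufa <- 100 * sum(p[c("oleic_pool", "linoleic", "alpha_linolenic",
                       "cla_ct", "cla_tt", "caproleic")])
  c(alpha_linolenic = 100 * p[["alpha_linolenic"]],
    linoleic = 100 * p[["linoleic"]],
    cla_ct = 100 * p[["cla_ct"]],
    cla_tt = 100 * p[["cla_tt"]],
    caproleic = 100 * p[["caproleic"]],
    ufa = ufa, sfa = 100 - ufa,
    mufa = 100 * (p[["oleic_pool"]] + p[["caproleic"]]))
}

# independent two-sided Fisher oracle: exhaustive hypergeometric enumeration
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  a_min <- max(0L, c1 - r2); a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - a_min + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# planted-marker cohort: classes differ only in CLA / linoleic /
# alpha-linolenic / caproleic, rebalanced through the oleic pool
planted_marker_spec <- function(seed = 42, n = 15) {
  p_hi <- fa_profile(butyric = 0.10, saturated_pool = 0.63,
                     oleic_pool = 0.214, linoleic = 0.030,
                     alpha_linolenic = 0.012, cla_ct = 0.010,
                     cla_tt = 0.002, caproleic = 0.002)
  p_lo <- fa_profile(butyric = 0.10, saturated_pool = 0.63,
                     oleic_pool = 0.232, linoleic = 0.020,
                     alpha_linolenic = 0.007, cla_ct = 0.005,
                     cla_tt = 0.001, caproleic = 0.005)
  cohort_spec(n_per_class = n,
              class_presets = list(organic = p_hi, conventional = p_lo),
              lipid_scale = list(organic = 1, conventional = 1),
              composition_jitter_sd = 0.05, seed = seed)
}

# small synthetic two-class matrix with a known informative structure
separable_matrix <- function(n_per_class = 10, p = 40, delta = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  cls <- rep(c("a", "b"), each = n_per_class)
  x[cls == "b", 1:3] <- x[cls == "b", 1:3] + delta
  list(x = x, classes = factor(cls))
}
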