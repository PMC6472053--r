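#' Fatty-acid composition of an acyl-chain pool
#'
#' Mole fractions per acyl chain of the eight species the pipeline tracks:
#' butyric (4:0), a lumped saturated pool (6:0-18:0), a lumped
#' internal-double-bond MUFA pool (dominated by oleic), linoleic
#' (18:2 n-6), alpha-linolenic (18:3 n-3), the co-resonating cis/trans CLA
#' isomers (9c11t + 9t11c + 10t12c), trans,trans CLA (9t11t) and caproleic
#' (9-decenoic, the only milk MUFA with a terminal double bond).
#'
#' @param butyric,saturated_pool,oleic_pool,linoleic,alpha_linolenic,cla_ct,cla_tt,caproleic
#'   non-negative mole fractions; must sum to 1 within `tol` unless
#'   `renormalize = TRUE`.
#' @param renormalize divide by the sum instead of requiring sum == 1.
#' @param tol tolerance on the unit-sum check.
#' @return named numeric vector of class `fa_profile`.
#' @export
#' @examples
#' fa_profile(butyric = 0.1, saturated_pool = 0.62, oleic_pool = 0.225,
#'            linoleic = 0.0305, alpha_linolenic = 0.0105, cla_ct = 0.01,
#'            cla_tt = 0.002, caproleic = 0.002)
fa_profile <- function(butyric = 0, saturated_pool = 0, oleic_pool = 0,
                       linoleic = 0, alpha_linolenic = 0, cla_ct = 0,
                       cla_tt = 0, caproleic = 0, renormalize = FALSE,
                       tol = 1e-9) {
  p <- c(butyric = butyric, saturated_pool = saturated_pool,
         oleic_pool = oleic_pool, linoleic = linoleic,
         alpha_linolenic = alpha_linolenic, cla_ct = cla_ct,
         cla_tt = cla_tt, caproleic = caproleic)
  if (anyNA(p) || any(p < 0)) stop("mole fractions must be >= 0", call. = FALSE)
  s <- sum(p)
  if (renormalize) {
    if (s <= 0) stop("cannot renormalize an all-zero profile", call. = FALSE)
    p <- p / s
  } else if (abs(s - 1) > tol) {
    stop(sprintf("mole fractions sum to %.10f, not 1", s), call. = FALSE)
  }
  structure(p, class = "fa_profile")
}

#' Organic / conventional milk composition presets
#'
#' Default class presets for cohort simulation, patterned on the reported
#' contrasts between organic and conventional bovine milk: organic milk
#' carries more CLA, linoleic and alpha-linolenic acid and ~28 mol% total
#' unsaturation; conventional milk carries more caproleic acid and ~24 mol%
#' unsaturation, with omega-6:omega-3 ratios near 2.9 (organic) and 2.75
#' (conventional).
#'
#' @param class `"organic"` or `"conventional"`.
#' @return an [fa_profile()].
#' @export
#' @examples
#' milk_preset("organic")
milk_preset <- function(class = c("organic", "conventional")) {
  class <- match.arg(class)
  if (class == "organic") {
    fa_profile(butyric = 0.1000, saturated_pool = 0.6200,
               oleic_pool = 0.2250, linoleic = 0.0305,
               alpha_linolenic = 0.0105, cla_ct = 0.0100,
               cla_tt = 0.0020, caproleic = 0.0020)
  } else {
    fa_profile(butyric = 0.1040, saturated_pool = 0.6560,
               oleic_pool = 0.1995, linoleic = 0.0220,
               alpha_linolenic = 0.0080, cla_ct = 0.0060,
               cla_tt = 0.0010, caproleic = 0.0035)
  }
}

#' Acquisition parameters for spectrum simulation
#'
#' @param recycle_time_s recycle time TR in s (acquisition + relaxation
#'   delay); default 9.3 s.
#' @param flip_angle_deg excitation pulse angle in degrees; default 30.
#' @param spectrometer_mhz proton frequency in MHz; default 500.
#' @param fwhm_hz Lorentzian full width at half maximum in Hz; default
#'   0.8 Hz (approximately 0.5 Hz natural linewidth of well-shimmed lipid
#'   extract resonances in CDCl3 plus 0.3 Hz exponential broadening).
#' @param noise_sd additive Gaussian noise standard deviation, in the
#'   intensity units in which a single proton at unit lipid scale has unit
#'   area; default 0.05.
#' @param n_points axis length (>= 4096); default 16384.
#' @param ppm_range numeric `c(lo, hi)` ppm; default `c(-0.5, 7)`.
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(recycle_time_s = 9.3, flip_angle_deg = 30,
                               spectrometer_mhz = 500, fwhm_hz = 0.8,
                               noise_sd = 0.05, n_points = 16384L,
                               ppm_range = c(-0.5, 7)) {
  stopifnot(recycle_time_s > 0, flip_angle_deg > 0, flip_angle_deg <= 90,
            spectrometer_mhz > 0, fwhm_hz > 0, noise_sd >= 0)
  n_points <- as.integer(n_points)
  if (n_points < 4096L) stop("n_points must be >= 4096", call. = FALSE)
  ppm_range <- sort(as.numeric(ppm_range))
  if (length(ppm_range) != 2L || diff(ppm_range) <= 0) {
    stop("ppm_range must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(recycle_time_s = recycle_time_s,
                 flip_angle_deg = flip_angle_deg,
                 spectrometer_mhz = spectrometer_mhz, fwhm_hz = fwhm_hz,
                 noise_sd = noise_sd, n_points = n_points,
                 ppm_range = ppm_range),
            class = "acquisition_params")
}

#' Steady-state longitudinal magnetization fraction
#'
#' Fraction of equilibrium z-magnetization available per scan for repeated
#' pulsing at flip angle theta with recycle time TR and relaxation time T1:
#' \deqn{f = (1 - E) / (1 - E \cos\theta), \quad E = e^{-TR/T_1}.}
#' With TR = 9.3 s, a 30 degree pulse and the slowest milk lipid T1 of
#' 3.2 s this evaluates to ~0.992, i.e. effectively complete relaxation.
#'
#' @param t1_s longitudinal relaxation time in s (> 0).
#' @param recycle_time_s recycle time TR in s (> 0).
#' @param flip_angle_deg pulse angle in degrees (0, 90].
#' @return fraction in (0, 1]; vectorised over `t1_s`.
#' @export
#' @examples
#' steady_state_factor(3.2, 9.3, 30)  # ~0.992
steady_state_factor <- function(t1_s, recycle_time_s, flip_angle_deg) {
  if (any(!is.finite(t1_s)) || any(t1_s <= 0)) {
    stop("t1_s must be positive", call. = FALSE)
  }
  if (!is.finite(recycle_time_s) && !identical(recycle_time_s, Inf)) {
    stop("recycle_time_s must be positive", call. = FALSE)
  }
  if (recycle_time_s <= 0) stop("recycle_time_s must be positive", call. = FALSE)
  if (flip_angle_deg <= 0 || flip_angle_deg > 90) {
    stop("flip_angle_deg must be in (0, 90]", call. = FALSE)
  }
  e <- exp(-recycle_time_s / t1_s)
  (1 - e) / (1 - e * cos(flip_angle_deg * pi / 180))
}

# first-order multiplet line positions/weights from couplings (Hz).
# each coupling entry is one coupled spin-1/2; repeated values give the
# binomial patterns (e.g. c(7.2, 7.2) -> 1:2:1 triplet).
multiplet_lines <- function(couplings_hz) {
  offs <- 0; w <- 1
  for (j in couplings_hz) {
    offs <- c(offs - j / 2, offs + j / 2)
    w <- c(w / 2, w / 2)
  }
  agg <- tapply(w, round(offs, 9), sum)
  list(offset_hz = as.numeric(names(agg)), weight = as.numeric(agg))
}

# unit-area Lorentzian on a ppm axis
lorentzian <- function(ppm, center, fwhm_ppm) {
  hw <- fwhm_ppm / 2
  (hw / pi) / ((ppm - center)^2 + hw^2)
}

#' Simulate a 1D 1H spectrum of a milk lipid extract
#'
#' Forward model: each assignment of each species present in `profile`
#' contributes a (possibly first-order-split) Lorentzian whose area is
#' mole fraction x protons per chain x `lipid_scale` x the steady-state
#' relaxation factor for its T1 under the acquisition parameters. Glycerol
#' backbone signals are added at one backbone per three chains (TAG) plus a
#' small 1,2-DAG contribution, and the hexamethylcyclotrisiloxane chemical
#' shift reference is placed at 0.172 ppm. Gaussian noise of sd
#' `params$noise_sd` is added; the result is deterministic given `seed`.
#'
#' @param profile an [fa_profile()].
#' @param params an [acquisition_params()].
#' @param lipid_scale multiplicative total-lipid factor (> 0), modelling
#'   e.g. 1.5\% vs 3\% fat content.
#' @param seed integer RNG seed for the noise (optional).
#' @param assignments assignment table (defaults to [assignment_table()]).
#' @param backbone include glycerol backbone signals.
#' @param dag_fraction backbone fraction present as 1,2-DAG.
#' @param reference include the 0.172 ppm shift reference (fixed area,
#'   independent of `lipid_scale`).
#' @return an `nmr_spectrum`.
#' @export
#' @examples
#' sp <- simulate_spectrum(milk_preset("organic"), seed = 1)
simulate_spectrum <- function(profile, params = acquisition_params(),
                              lipid_scale = 1, seed = NULL,
                              assignments = assignment_table(),
                              backbone = TRUE, dag_fraction = 0.02,
                              reference = TRUE) {
  stopifnot(inherits(profile, "fa_profile"),
            inherits(params, "acquisition_params"))
  if (!is.finite(lipid_scale) || lipid_scale <= 0) {
    stop("lipid_scale must be positive", call. = FALSE)
  }
  validate_assignments(assignments)

  weight_for <- function(species) {
    if (species %in% names(profile)) return(unname(profile[species]))
    if (species == "tag_backbone") return((1 - dag_fraction) / 3)
    if (species == "dag_backbone") return(dag_fraction / 3)
    0
  }
  use <- vapply(assignments$species_id, weight_for, numeric(1)) > 0
  act <- assignments[use, , drop = FALSE]
  rng <- range(act$shift_ppm)
  if (rng[1] < params$ppm_range[1] || rng[2] > params$ppm_range[2]) {
    stop(sprintf("ppm_range [%.2f, %.2f] does not cover assignments (%.2f-%.2f ppm)",
                 params$ppm_range[1], params$ppm_range[2], rng[1], rng[2]),
         call. = FALSE)
  }

  ppm <- seq(params$ppm_range[2], params$ppm_range[1],
             length.out = params$n_points)          # descending
  fwhm_ppm <- params$fwhm_hz / params$spectrometer_mhz
  intensity <- numeric(params$n_points)

  for (i in seq_len(nrow(act))) {
    w <- weight_for(act$species_id[i])
    area <- w * act$protons_per_chain[i] * lipid_scale *
      steady_state_factor(act$t1_s[i], params$recycle_time_s,
                          params$flip_angle_deg)
    ml <- multiplet_lines(act$multiplicity[[i]])
    for (k in seq_along(ml$offset_hz)) {
      ctr <- act$shift_ppm[i] + ml$offset_hz[k] / params$spectrometer_mhz
      intensity <- intensity +
        area * ml$weight[k] * lorentzian(ppm, ctr, fwhm_ppm)
    }
  }

  if (reference) {
    # hexamethylcyclotrisiloxane, fixed amount per tube
    intensity <- intensity + 0.5 * lorentzian(ppm, 0.172, fwhm_ppm)
  }
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    intensity <- intensity + stats::rnorm(params$n_points, 0, params$noise_sd)
  }

  nmr_spectrum(ppm, intensity,
               meta = list(params = params, lipid_scale = lipid_scale,
                           profile = unclass(profile), seed = seed))
}

#' Cohort design for two-class simulation
#'
#' @param n_per_class samples per class; scalar or named vector
#'   `c(organic = ..., conventional = ...)`.
#' @param class_presets named list of two [fa_profile()]s (`organic`,
#'   `conventional`).
#' @param lipid_scale named list of per-class total-lipid factors, recycled
#'   over the samples of each class. The default gives every organic sample
#'   the semi-skimmed factor 1 and alternates conventional samples between
#'   factors 1 and 2, mirroring a cohort whose conventional half is split
#'   between 1.5\% and 3\% fat.
#' @param composition_jitter_sd per-species relative (lognormal) standard
#'   deviation of the composition jitter; default 0.05.
#' @param seed RNG seed for the cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 20,
                        class_presets = list(organic = milk_preset("organic"),
                                             conventional = milk_preset("conventional")),
                        lipid_scale = list(organic = 1, conventional = c(1, 2)),
                        composition_jitter_sd = 0.05, seed = 1L) {
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- c(organic = n_per_class, conventional = n_per_class)
  }
  classes <- names(class_presets)
  if (length(classes) != 2L) stop("exactly two class presets required", call. = FALSE)
  if (!all(classes %in% names(n_per_class))) {
    stop("n_per_class must name both classes", call. = FALSE)
  }
  if (any(n_per_class < 2)) stop("n_per_class must be >= 2", call. = FALSE)
  for (cl in classes) {
    if (!inherits(class_presets[[cl]], "fa_profile")) {
      stop("class_presets must be fa_profile objects", call. = FALSE)
    }
    if (any(!is.finite(lipid_scale[[cl]])) || any(lipid_scale[[cl]] <= 0)) {
      stop("lipid_scale must be positive", call. = FALSE)
    }
  }
  if (composition_jitter_sd < 0) stop("composition_jitter_sd must be >= 0", call. = FALSE)
  structure(list(n_per_class = n_per_class, class_presets = class_presets,
                 lipid_scale = lipid_scale,
                 composition_jitter_sd = composition_jitter_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean-preserving lognormal jitter of a profile, then renormalization
jitter_profile <- function(preset, sd) {
  p <- unclass(preset)
  if (sd > 0) {
    p <- p * exp(stats::rnorm(length(p), -sd^2 / 2, sd))
  }
  fa_profile_from_vector(p / sum(p))
}

fa_profile_from_vector <- function(p) {
  do.call(fa_profile, as.list(p))
}

#' Simulate a two-class cohort of milk lipid spectra
#'
#' Each sample's ground-truth profile is its class preset perturbed by
#' mean-preserving lognormal jitter and renormalized; each spectrum is then
#' simulated with its class's lipid-scale factor. Reproducible from
#' `spec$seed` (per-sample noise seeds are drawn deterministically from it).
#'
#' @param spec a [cohort_spec()].
#' @param params an [acquisition_params()].
#' @return list with `spectra` (list of `nmr_spectrum`), `classes` (factor),
#'   `profiles` (list of `fa_profile` ground truths), `lipid_scales`
#'   (numeric) and `sample_ids`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_per_class = 2, seed = 7))
#' table(coh$classes)
simulate_cohort <- function(spec, params = acquisition_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  classes <- names(spec$class_presets)
  out_class <- character(0); profiles <- list(); scales <- numeric(0)
  for (cl in classes) {
    n <- spec$n_per_class[[cl]]
    sc <- rep_len(spec$lipid_scale[[cl]], n)
    for (i in seq_len(n)) {
      profiles[[length(profiles) + 1L]] <-
        jitter_profile(spec$class_presets[[cl]], spec$composition_jitter_sd)
    }
    out_class <- c(out_class, rep(cl, n))
    scales <- c(scales, sc)
  }
  n_tot <- length(out_class)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  spectra <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    spectra[[i]] <- simulate_spectrum(profiles[[i]], params,
                                      lipid_scale = scales[i],
                                      seed = noise_seeds[i])
  }
  ids <- sprintf("%s_%02d", substr(out_class, 1, 3),
                 stats::ave(seq_len(n_tot), out_class, FUN = seq_along))
  list(spectra = spectra, classes = factor(out_class, levels = classes),
       profiles = profiles, lipid_scales = scales, sample_ids = ids)
}

#' Write a simulated cohort to disk
#'
#' Writes one two-column CSV per spectrum plus `ground_truth.csv` holding
#' class labels, lipid scales and the seeded mole fractions.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$spectra)) {
    write_spectrum_csv(cohort$spectra[[i]],
                       file.path(dir, paste0(cohort$sample_ids[i], ".csv")))
  }
  gt <- data.frame(sample_id = cohort$sample_ids,
                   class = as.character(cohort$classes),
                   lipid_scale = cohort$lipid_scales,
                   do.call(rbind, lapply(cohort$profiles, unclass)))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
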