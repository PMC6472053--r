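#' Construct an integral set
#'
#' The ten named signal areas feeding the quantification equations:
#' \code{I088} and \code{I095} (terminal methyls; their sum \code{I_TL}
#' counts three protons per acyl chain and is the chain-count denominator),
#' \code{D} (allylic protons at 2.02 ppm), \code{C} (alpha-carbonyl C2
#' protons at 2.33 ppm), \code{I277}/\code{I281} (bis-allylic protons of
#' linoleic / alpha-linolenic acid), \code{I499}/\code{I580} (caproleic
#' terminal vinyl H10a / H9), \code{I599} (trans,trans CLA H10+H11) and
#' \code{I628} (cis,trans CLA H11).
#'
#' Negative areas (possible under noise) are floored at zero with a
#' warning before any equation is applied.
#'
#' @param values named list or vector holding the ten integrals.
#' @param windows optional window table recorded as provenance.
#' @return object of class `integral_set`.
#' @export
integral_set <- function(values, windows = NULL) {
  need <- c("I088", "I095", "D", "C", "I277", "I281",
            "I499", "I580", "I599", "I628")
  values <- as.list(values)
  missing <- setdiff(need, names(values))
  if (length(missing)) {
    stop("integral set missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- vapply(values[need], as.numeric, numeric(1))
  if (anyNA(v) || any(!is.finite(v))) {
    stop("integrals must be finite", call. = FALSE)
  }
  if (any(v < 0)) {
    warning("negative integral(s) floored at 0: ",
            paste(need[v < 0], collapse = ", "), call. = FALSE)
    v[v < 0] <- 0
  }
  structure(as.list(v), windows = windows, class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat("<integral_set>\n")
  print(unlist(x))
  invisible(x)
}

i_tl <- function(I, require_positive = TRUE) {
  tl <- I$I088 + I$I095
  if (require_positive && tl <= 0) {
    stop("total methyl integral I_TL = I0.88 + I0.95 must be positive",
         call. = FALSE)
  }
  tl
}

as_integral_set <- function(I) {
  if (inherits(I, "integral_set")) I else integral_set(I)
}

#' Mole percentages of individual fatty acids from signal integrals
#'
#' Integral-ratio estimates of the minor unsaturated acids as mole percent
#' of (methyl-bearing) acyl chains. With \code{I_TL = I0.88 + I0.95} (three
#' methyl protons per chain):
#' \itemize{
#'   \item alpha-linolenic: \code{100 * 3 I2.81 / (4 I_TL)} (4 bis-allylic
#'     protons per chain);
#'   \item linoleic: \code{100 * 3 I2.77 / (2 I_TL)} (2 bis-allylic protons);
#'   \item cis/trans CLA isomers: \code{100 * 3 I6.28 / I_TL} (one
#'     conjugated-diene proton at 6.28 ppm);
#'   \item trans,trans CLA: \code{100 * 3 I5.99 / (2 I_TL)} (H10 + H11);
#'   \item caproleic: \code{100 * 3 I5.80 / I_TL} from H9 and
#'     \code{100 * 3 I4.99 / I_TL} from H10a — two independent one-proton
#'     estimates that should agree.
#' }
#'
#' @param I an `integral_set` (or coercible named list).
#' @return percentage (for [pct_caproleic()], a named vector of the two
#'   estimates `from_H9` and `from_H10a`; a warning is emitted when they
#'   disagree by more than 10\% relative).
#' @name pct_fatty_acids
NULL

#' @rdname pct_fatty_acids
#' @export
pct_alpha_linolenic <- function(I) {
  I <- as_integral_set(I)
  100 * 3 * I$I281 / (4 * i_tl(I))
}

#' @rdname pct_fatty_acids
#' @export
pct_linoleic <- function(I) {
  I <- as_integral_set(I)
  100 * 3 * I$I277 / (2 * i_tl(I))
}

#' @rdname pct_fatty_acids
#' @export
pct_cla_ct <- function(I) {
  I <- as_integral_set(I)
  100 * 3 * I$I628 / i_tl(I)
}

#' @rdname pct_fatty_acids
#' @export
pct_cla_tt <- function(I) {
  I <- as_integral_set(I)
  100 * 3 * I$I599 / (2 * i_tl(I))
}

#' @rdname pct_fatty_acids
#' @export
pct_caproleic <- function(I) {
  I <- as_integral_set(I)
  tl <- i_tl(I)
  est <- c(from_H9 = 100 * 3 * I$I580 / tl,
           from_H10a = 100 * 3 * I$I499 / tl)
  m <- mean(est)
  if (m > 0 && abs(est[1] - est[2]) / m > 0.10) {
    warning(sprintf(
      "caproleic estimates from H9 (%.3f%%) and H10a (%.3f%%) disagree by more than 10%% relative",
      est[1], est[2]), call. = FALSE)
  }
  est
}

#' Total, mono- and saturated fatty acid percentages
#'
#' Total unsaturation from the allylic (\code{D}) and alpha-carbonyl
#' (\code{C}) integrals with a terminal-double-bond correction for
#' caproleic acid:
#' \deqn{UFA\% = 100 (D + 2 I_{4.99}) / (2 C).}
#' Every internal double bond carries 4 allylic protons into \code{D};
#' caproleic's terminal double bond carries only 2, so its share is
#' completed from the one-proton 4.99 ppm integral (adding
#' \code{2 I4.99} restores 4 proton-equivalents per caproleic chain);
#' every chain contributes 2 protons to \code{C}. The pure-oleic and
#' pure-caproleic limits both evaluate to 100\%. SFA is the complement
#' (\code{100 - UFA}); MUFA subtracts the individually quantified
#' polyunsaturated and CLA percentages from UFA.
#'
#' If \code{D < 2 I4.99} (impossible for a real composition, reachable
#' under noise) \code{D} is clipped to the caproleic-only floor
#' \code{2 I4.99} with a warning. Results are clipped to `[0, 100]`
#' (with a warning) so that percentages stay interpretable under noise.
#'
#' @param I an `integral_set` (or coercible named list).
#' @return percentage.
#' @name pct_totals
NULL

#' @rdname pct_totals
#' @export
pct_ufa <- function(I) {
  I <- as_integral_set(I)
  if (I$C <= 0) stop("alpha-carbonyl integral C must be positive", call. = FALSE)
  D <- I$D
  if (D < 2 * I$I499) {
    warning("allylic integral D below the caproleic-only floor 2*I4.99; clipped",
            call. = FALSE)
    D <- 2 * I$I499
  }
  ufa <- 100 * (D + 2 * I$I499) / (2 * I$C)
  if (ufa > 100) {
    warning(sprintf("UFA estimate %.2f%% clipped to 100%%", ufa), call. = FALSE)
    ufa <- 100
  }
  ufa
}

#' @rdname pct_totals
#' @export
pct_sfa <- function(I) {
  100 - pct_ufa(I)
}

#' @rdname pct_totals
#' @export
pct_mufa <- function(I) {
  I <- as_integral_set(I)
  mufa <- pct_ufa(I) - pct_linoleic(I) - pct_alpha_linolenic(I) -
    pct_cla_ct(I) - pct_cla_tt(I)
  if (mufa < 0) {
    warning(sprintf("MUFA estimate %.2f%% clipped to 0%%", mufa), call. = FALSE)
    mufa <- 0
  }
  mufa
}

#' Omega-6 : omega-3 ratio
#'
#' Ratio of the linoleic (omega-6) to the alpha-linolenic (omega-3)
#' percentage; the integral factors cancel to \code{2 I2.77 / I2.81}.
#'
#' @param I an `integral_set` (or coercible named list).
#' @return dimensionless ratio.
#' @export
omega_ratio <- function(I) {
  I <- as_integral_set(I)
  if (I$I281 <= 0) {
    stop("omega-6:omega-3 ratio undefined: I2.81 is zero", call. = FALSE)
  }
  2 * I$I277 / I$I281
}

#' Full composition report from an integral set
#'
#' @param I an `integral_set` (or coercible named list).
#' @param caproleic_from which caproleic estimate to report
#'   (`"H9"`, `"H10a"` or their `"mean"`).
#' @return one-row data frame with columns `alpha_linolenic`, `linoleic`,
#'   `cla_ct`, `cla_tt`, `caproleic`, `ufa`, `mufa`, `sfa` (mole \% of acyl
#'   chains) and `omega_ratio`.
#' @export
#' @examples
#' sp <- simulate_spectrum(milk_preset("organic"), seed = 1)
#' composition_report(extract_integral_set(sp))
composition_report <- function(I, caproleic_from = c("mean", "H9", "H10a")) {
  caproleic_from <- match.arg(caproleic_from)
  I <- as_integral_set(I)
  cap <- pct_caproleic(I)
  cap_val <- switch(caproleic_from, mean = mean(cap),
                    H9 = unname(cap["from_H9"]),
                    H10a = unname(cap["from_H10a"]))
  data.frame(
    alpha_linolenic = pct_alpha_linolenic(I),
    linoleic = pct_linoleic(I),
    cla_ct = pct_cla_ct(I),
    cla_tt = pct_cla_tt(I),
    caproleic = cap_val,
    ufa = pct_ufa(I),
    mufa = pct_mufa(I),
    sfa = pct_sfa(I),
    omega_ratio = if (I$I281 > 0) omega_ratio(I) else NA_real_
  )
}

#' Repeatability statistics of replicate measurements
#'
#' Coefficient of variation \code{cv = 100 sd / mean} (sample standard
#' deviation) and the derived precision \code{prec = 1 - sd/mean}; a CV of
#' 1.5\% corresponds to a precision of 0.985.
#'
#' @param values numeric vector of replicate measurements (>= 2 values,
#'   non-zero mean).
#' @return named numeric `c(cv_percent, precision)`.
#' @export
#' @examples
#' precision_stats(c(9, 10, 11))  # cv 10%, precision 0.9
precision_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 replicate values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero", call. = FALSE)
  rsd <- stats::sd(values) / m
  c(cv_percent = 100 * rsd, precision = 1 - rsd)
}

#' Percent relative deviation from a reference value
#'
#' @param test_value measured value.
#' @param reference_value non-zero reference.
#' @return `100 * (test - reference) / reference`.
#' @export
relative_deviation <- function(test_value, reference_value) {
  if (any(reference_value == 0)) stop("reference value must be non-zero", call. = FALSE)
  100 * (test_value - reference_value) / reference_value
}
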