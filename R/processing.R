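# cumulative trapezoidal integral of the piecewise-linear interpolant of
# (x, y), evaluated exactly at arbitrary positions; x ascending. Shared by
# window integration and bucketing so that adjacent regions partition the
# total area exactly.
piecewise_cum <- function(x, y) {
  n <- length(x)
  cum <- c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
  function(v) {
    i <- findInterval(v, x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    yl <- y[i] + (y[i + 1L] - y[i]) * (v - x[i]) / (x[i + 1L] - x[i])
    cum[i] + (v - x[i]) * (y[i] + yl) / 2
  }
}

# exact integral of the piecewise-linear interpolant of (x, y) over [lo, hi]
trapz_between <- function(x, y, lo, hi) {
  n <- length(x)
  if (lo < x[1] || hi > x[n]) stop("integration bounds outside axis", call. = FALSE)
  if (hi <= lo) return(0)
  f <- piecewise_cum(x, y)
  f(hi) - f(lo)
}

ascending <- function(spectrum) {
  list(x = rev(spectrum$ppm), y = rev(spectrum$intensity))
}

#' Recalibrate the chemical shift axis against the internal reference
#'
#' Locates the maximum within `search_ppm` of the nominal reference
#' position (0.172 ppm, hexamethylcyclotrisiloxane) and translates the axis
#' so that the maximum sits exactly at the nominal position. The candidate
#' maximum must rise clearly above the spectrum's robust baseline
#' (median + 10 x MAD); otherwise the reference is declared not found.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param reference_ppm nominal reference position; default 0.172.
#' @param search_ppm half-width of the search interval; default 0.05 ppm.
#' @return the recalibrated `nmr_spectrum`, with the applied shift recorded
#'   in `meta$reference_shift_ppm`.
#' @export
reference_shift <- function(spectrum, reference_ppm = 0.172,
                            search_ppm = 0.05) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  sel <- which(spectrum$ppm >= reference_ppm - search_ppm &
                 spectrum$ppm <= reference_ppm + search_ppm)
  if (!length(sel)) stop("axis does not cover the reference region", call. = FALSE)
  peak_i <- sel[which.max(spectrum$intensity[sel])]
  height <- spectrum$intensity[peak_i]
  base <- stats::median(spectrum$intensity)
  spread <- stats::mad(spectrum$intensity)
  if (!(height - base > 10 * spread) || height <= base) {
    stop("reference not found near ", reference_ppm, " ppm", call. = FALSE)
  }
  delta <- reference_ppm - spectrum$ppm[peak_i]
  out <- spectrum
  out$ppm <- spectrum$ppm + delta
  out$meta$reference_shift_ppm <- delta
  out
}

#' Integrate a spectrum over a ppm window
#'
#' Trapezoidal area of the intensity over `[lo_ppm, hi_ppm)` on the native
#' axis (no resampling), with exact linear interpolation at the window
#' bounds. Optionally subtracts a linear baseline through the window
#' endpoints.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param lo_ppm,hi_ppm window bounds in ppm, `lo_ppm < hi_ppm`; both must
#'   lie inside the axis range.
#' @param baseline `"none"` (default, the spectrum is assumed
#'   baseline-corrected) or `"linear"` (subtract the chord through the
#'   endpoint intensities).
#' @return the integral in intensity x ppm units.
#' @export
#' @examples
#' sp <- nmr_spectrum(seq(0, 1, by = 0.001), rep(1, 1001))
#' integrate_window(sp, 0.2, 0.3)  # unit-height rectangle -> 0.1
integrate_window <- function(spectrum, lo_ppm, hi_ppm,
                             baseline = c("none", "linear")) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  baseline <- match.arg(baseline)
  if (lo_ppm >= hi_ppm) stop("lo_ppm must be < hi_ppm", call. = FALSE)
  a <- ascending(spectrum)
  if (lo_ppm < a$x[1] || hi_ppm > a$x[length(a$x)]) {
    stop(sprintf("window [%g, %g] outside axis range [%g, %g]",
                 lo_ppm, hi_ppm, a$x[1], a$x[length(a$x)]), call. = FALSE)
  }
  area <- trapz_between(a$x, a$y, lo_ppm, hi_ppm)
  if (baseline == "linear") {
    y_at <- stats::approx(a$x, a$y, xout = c(lo_ppm, hi_ppm))$y
    area <- area - mean(y_at) * (hi_ppm - lo_ppm)
  }
  area
}

#' Extract the ten named quantification integrals
#'
#' Integrates the spectrum over each window of [integration_windows()] and
#' returns them under the integral-set field names used by the
#' quantification equations (`I088`, `I095`, `D` = allylic, `C` =
#' alpha-carbonyl, `I277`, `I281`, `I499`, `I580`, `I599`, `I628`).
#'
#' @param spectrum an `nmr_spectrum`.
#' @param windows window table from [integration_windows()]; all ten
#'   windows must be present.
#' @param baseline passed to [integrate_window()].
#' @return an `integral_set` (named list) with the window table attached as
#'   attribute `windows`.
#' @export
extract_integral_set <- function(spectrum, windows = integration_windows(),
                                 baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  field_map <- c("I0.88" = "I088", "I0.95" = "I095", "I2.02" = "D",
                 "I2.33" = "C", "I2.77" = "I277", "I2.81" = "I281",
                 "I4.99" = "I499", "I5.80" = "I580", "I5.99" = "I599",
                 "I6.28" = "I628")
  missing <- setdiff(names(field_map), windows$name)
  if (length(missing)) {
    stop("missing integration window(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_windows(windows)
  vals <- vapply(names(field_map), function(nm) {
    w <- windows[windows$name == nm, ]
    integrate_window(spectrum, w$lo_ppm, w$hi_ppm, baseline = baseline)
  }, numeric(1))
  names(vals) <- unname(field_map)
  integral_set(as.list(vals), windows = windows)
}

#' Fixed-size bucketing of a spectrum
#'
#' Segments the region `lo` to `hi` ppm into `width`-ppm half-open bins
#' `[left, right)` (left edges at `lo + width * k`) and returns the
#' trapezoidal area of the spectrum over each bin. The default reproduces
#' the conventional 0.01-ppm bucketing of the 0.03-6.34 ppm region,
#' yielding 631 buckets. Bins partition the region exactly: their sum
#' equals the integral over `[lo, hi]`.
#'
#' @param spectrum an `nmr_spectrum`; the axis must cover `[lo, hi]`.
#' @param lo,hi,width bucketing region and bin width, in ppm.
#' @return numeric vector of bucket areas with attributes `edges` (length
#'   `n + 1`) and `centers` (length `n`).
#' @export
#' @examples
#' sp <- simulate_spectrum(milk_preset("organic"), seed = 1)
#' b <- bucket_spectrum(sp)
#' length(b)  # 631
bucket_spectrum <- function(spectrum, lo = 0.03, hi = 6.34, width = 0.01) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  n_bins <- round((hi - lo) / width)
  if (n_bins < 1 || abs(lo + n_bins * width - hi) > 1e-8) {
    stop("bucket region is not a whole number of bins", call. = FALSE)
  }
  a <- ascending(spectrum)
  if (lo < a$x[1] || hi > a$x[length(a$x)]) {
    stop(sprintf("axis [%g, %g] does not cover bucket region [%g, %g]",
                 a$x[1], a$x[length(a$x)], lo, hi), call. = FALSE)
  }
  edges <- lo + width * (0:n_bins)
  vals <- diff(piecewise_cum(a$x, a$y)(edges))
  structure(vals, edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2)
}

#' Assemble a bucket matrix from a list of spectra
#'
#' @param spectra list of `nmr_spectrum` objects.
#' @param classes factor/character of class labels, one per spectrum.
#' @param sample_ids optional sample identifiers.
#' @param lo,hi,width passed to [bucket_spectrum()].
#' @return object of class `bucket_matrix`: list with `values` (samples x
#'   bins matrix), `centers`, `edges`, `classes`, `sample_ids` and
#'   `normalization` (`"UNor"` initially).
#' @export
bucket_matrix <- function(spectra, classes, sample_ids = NULL,
                          lo = 0.03, hi = 6.34, width = 0.01) {
  stopifnot(length(spectra) == length(classes))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_along(spectra))
  rows <- lapply(spectra, bucket_spectrum, lo = lo, hi = hi, width = width)
  values <- do.call(rbind, lapply(rows, as.numeric))
  rownames(values) <- sample_ids
  centers <- attr(rows[[1]], "centers")
  colnames(values) <- sprintf("ppm_%.3f", centers)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("bucket matrix contains non-finite values", call. = FALSE)
  }
  structure(list(values = values, centers = centers,
                 edges = attr(rows[[1]], "edges"),
                 classes = factor(classes), sample_ids = sample_ids,
                 normalization = "UNor"),
            class = "bucket_matrix")
}

#' @export
print.bucket_matrix <- function(x, ...) {
  cat(sprintf("<bucket_matrix> %d samples x %d buckets (%s), classes: %s\n",
              nrow(x$values), ncol(x$values), x$normalization,
              paste(sprintf("%s=%d", levels(x$classes),
                            tabulate(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Indices of the methyl (I0.88 + I0.95) buckets
#'
#' Buckets whose centers fall inside the two terminal-methyl integration
#' windows; their row sum plays the role of the total methyl integral in
#' NorCont normalization.
#'
#' @param centers bucket center positions (ppm).
#' @param windows window table from [integration_windows()].
#' @return integer vector of bucket indices.
#' @export
methyl_bucket_indices <- function(centers, windows = integration_windows()) {
  w <- windows[windows$name %in% c("I0.88", "I0.95"), ]
  which(vapply(centers, function(p) {
    any(p >= w$lo_ppm & p < w$hi_ppm)
  }, logical(1)))
}

#' Write a bucket matrix to CSV
#'
#' Samples x bins with a header of bin centers, preceded by sample id and
#' class columns.
#'
#' @param bm a `bucket_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bucket_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "bucket_matrix"))
  df <- data.frame(sample_id = bm$sample_ids, class = as.character(bm$classes),
                   bm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a bucket matrix from CSV
#'
#' @param path file written by [write_bucket_matrix()].
#' @param normalization tag to record (`"UNor"` or `"NorCont"`).
#' @return a `bucket_matrix`.
#' @export
read_bucket_matrix <- function(path, normalization = "UNor") {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$sample_id
  centers <- as.numeric(sub("^ppm_", "", colnames(values)))
  width <- stats::median(diff(centers))
  structure(list(values = values, centers = centers,
                 edges = c(centers - width / 2, centers[length(centers)] + width / 2),
                 classes = factor(df$class), sample_ids = df$sample_id,
                 normalization = normalization),
            class = "bucket_matrix")
}
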