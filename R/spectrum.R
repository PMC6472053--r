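#' Construct a 1D NMR spectrum object
#'
#' A spectrum is a strictly monotonic ppm axis (stored descending, the NMR
#' display convention) with a same-length intensity vector and a metadata
#' list.
#'
#' @param ppm numeric axis in ppm (ascending or descending; stored
#'   descending).
#' @param intensity numeric intensities, same length as `ppm`.
#' @param meta named list of acquisition metadata.
#' @return object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, meta = list()) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have the same length", call. = FALSE)
  }
  if (length(ppm) < 2L) stop("spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(ppm) || anyNA(intensity)) stop("spectrum contains NA", call. = FALSE)
  d <- diff(ppm)
  if (all(d > 0)) {           # ascending in: flip to descending
    ppm <- rev(ppm); intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotonic", call. = FALSE)
  }
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f to %.3f ppm\n",
              length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Read / write a spectrum as two-column CSV (ppm, intensity)
#'
#' @param path file path.
#' @param spectrum an `nmr_spectrum`.
#' @return `read_spectrum_csv()` returns an `nmr_spectrum`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected two columns (ppm, intensity)", call. = FALSE)
  nmr_spectrum(df[[1]], df[[2]], meta = list(source = path))
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a spectrum in minimal JCAMP-DX (AFFN, X++(Y..Y)) form
#'
#' Covers the simple fixed-step JCAMP-DX layout used for exchanging 1D
#' spectra: XFACTOR/YFACTOR scaling, one X value followed by Y values per
#' line. Not a general JCAMP-DX parser (no compression schemes).
#'
#' @param path file path.
#' @param spectrum an `nmr_spectrum`.
#' @param title record title.
#' @return `read_jcamp()` returns an `nmr_spectrum`; `write_jcamp()` returns
#'   `path` invisibly.
#' @export
write_jcamp <- function(spectrum, path, title = "milknmr spectrum") {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  ppm <- spectrum$ppm; y <- spectrum$intensity
  n <- length(ppm)
  yfac <- max(abs(y), 1e-12) / 1e7
  yi <- y / yfac
  con <- file(path, "w"); on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("##TITLE=%s", title)
  wr("##JCAMP-DX=4.24")
  wr("##DATA TYPE=NMR SPECTRUM")
  wr("##XUNITS=PPM")
  wr("##YUNITS=ARBITRARY")
  wr("##XFACTOR=1")
  wr("##YFACTOR=%.10e", yfac)
  wr("##FIRSTX=%.10f", ppm[1])
  wr("##LASTX=%.10f", ppm[n])
  wr("##NPOINTS=%d", n)
  wr("##FIRSTY=%.10e", y[1])
  wr("##XYDATA=(X++(Y..Y))")
  per <- 6L
  for (i in seq(1L, n, by = per)) {
    j <- min(i + per - 1L, n)
    writeLines(paste(c(sprintf("%.6f", ppm[i]),
                       sprintf("%.4f", yi[i:j])), collapse = " "), con)
  }
  wr("##END=")
  invisible(path)
}

#' @rdname write_jcamp
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field <- function(key) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^##", key, "="), "", ln[1])
  }
  firstx <- as.numeric(field("FIRSTX"))
  lastx <- as.numeric(field("LASTX"))
  npt <- as.integer(field("NPOINTS"))
  yfac <- as.numeric(field("YFACTOR"))
  if (anyNA(c(firstx, lastx, npt, yfac))) {
    stop("not a recognised JCAMP-DX file: ", path, call. = FALSE)
  }
  start <- grep("^##XYDATA", lines)
  end <- grep("^##END", lines)
  if (!length(start) || !length(end)) stop("missing XYDATA block", call. = FALSE)
  data_lines <- lines[(start + 1L):(end - 1L)]
  y <- unlist(lapply(strsplit(trimws(data_lines), "[[:space:]]+"), function(v) {
    as.numeric(v[-1])       # first token on each line is the X value
  }))
  if (length(y) != npt) {
    stop("JCAMP NPOINTS (", npt, ") does not match data (", length(y), ")",
         call. = FALSE)
  }
  ppm <- seq(firstx, lastx, length.out = npt)
  nmr_spectrum(ppm, y * yfac, meta = list(source = path))
}
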