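# Spectra: construction, delimited-text I/O, blank subtraction, Beer-Lambert
# conversion, peak location/shift reports and hyperchromicity ratios.

SPECTRUM_KINDS <- c("emission", "absorbance", "molar_absorptivity", "synchronous")

#' Construct a spectrum
#'
#' A spectrum is a sampled optical curve: a strictly increasing wavelength grid
#' (nm) plus a signal of the same length. The `kind` records what the signal
#' is — fluorescence emission (a.u.), absorbance (AU), molar absorptivity
#' (M^-1 cm^-1) or a synchronous fluorescence scan — and is used to enforce
#' non-negativity where it is physical (absorbance-like kinds).
#'
#' @param wavelengths_nm numeric, strictly increasing, length >= 2.
#' @param signal numeric, same length as `wavelengths_nm`.
#' @param kind one of `"emission"`, `"absorbance"`, `"molar_absorptivity"`,
#'   `"synchronous"`.
#' @param meta named list of optional metadata: `temperature_K`,
#'   `excitation_nm`, `delta_lambda_nm` (synchronous scans: the fixed offset
#'   between excitation and emission wavelength), `label`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths_nm, signal, kind = "emission", meta = list()) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 2L) {
    stop_format("a spectrum needs a numeric wavelength grid of length >= 2")
  }
  if (anyNA(wavelengths_nm) || anyNA(signal)) {
    stop_format("spectrum wavelengths and signal must not contain NA")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop_format("spectrum wavelengths must be strictly increasing")
  }
  if (!is.numeric(signal) || length(signal) != length(wavelengths_nm)) {
    stop_format("signal must be numeric and the same length as the grid")
  }
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (kind %in% c("absorbance", "molar_absorptivity") && any(signal < 0)) {
    stop_domain("%s spectra cannot carry negative values", kind)
  }
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         signal = as.numeric(signal),
         kind = kind,
         meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("<spectrum: %s, %d points, %.6g-%.6g nm%s>\n",
              x$kind, length(x$signal), rng[1], rng[2],
              if (!is.null(x$meta$label)) paste0(", ", x$meta$label) else ""))
  invisible(x)
}

## Split a delimited line on comma, tab or runs of whitespace.
split_fields <- function(line) {
  if (grepl(",", line, fixed = TRUE)) {
    strsplit(line, ",", fixed = TRUE)[[1L]]
  } else if (grepl("\t", line, fixed = TRUE)) {
    strsplit(line, "\t", fixed = TRUE)[[1L]]
  } else {
    strsplit(trimws(line), "[[:space:]]+")[[1L]]
  }
}

#' Read a spectrum from a two-column delimited text file
#'
#' The file must hold two numeric columns (wavelength in nm, signal), separated
#' by comma, tab or whitespace (autodetected), with at most one header line.
#' Rows are sorted by wavelength on read; duplicated wavelengths are rejected.
#'
#' @param path file path.
#' @param kind spectrum kind, see [spectrum()].
#' @param meta metadata list, see [spectrum()].
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = "emission", meta = list()) {
  if (!file.exists(path)) stop_format("spectrum file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("%s: empty spectrum file", path)

  parse_row <- function(line) suppressWarnings(as.numeric(split_fields(line)[1:2]))
  first <- parse_row(lines[1L])
  start <- if (anyNA(first)) 2L else 1L  # one optional header line
  if (length(lines) < start + 1L) {
    stop_format("%s: a spectrum needs at least 2 data rows", path)
  }
  wl <- numeric(0); sig <- numeric(0)
  for (i in seq(start, length(lines))) {
    v <- parse_row(lines[i])
    if (anyNA(v)) stop_format("%s: non-numeric data on line %d: '%s'", path, i, lines[i])
    wl <- c(wl, v[1L]); sig <- c(sig, v[2L])
  }
  dup <- duplicated(wl)
  if (any(dup)) {
    stop_format("%s: duplicate wavelength %.6g nm (line %d)",
                path, wl[dup][1L], which(dup)[1L] + start - 1L)
  }
  ord <- order(wl)
  spectrum(wl[ord], sig[ord], kind = kind, meta = meta)
}

#' Write a spectrum to a two-column delimited text file
#'
#' @param x a [spectrum()].
#' @param path output file path.
#' @param digits significant digits for formatting; defaults to full precision
#'   round-trip (`digits = 15`).
#' @param sep field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, digits = 15, sep = ",") {
  stopifnot(inherits(x, "spectrum"))
  header <- paste("wavelength_nm", "signal", sep = sep)
  rows <- paste(formatC(x$wavelengths_nm, digits = digits, format = "g"),
                formatC(x$signal, digits = digits, format = "g"), sep = sep)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Subtract a blank spectrum
#'
#' Pointwise subtraction of an instrument blank recorded on the identical
#' wavelength grid (within `grid_tol_nm`). Kind and metadata are inherited
#' from the sample.
#'
#' @param sample,blank [spectrum()] objects on the same grid.
#' @param grid_tol_nm maximum per-point wavelength discrepancy still treated
#'   as "the same grid" (default 1e-6 nm).
#' @return A [spectrum()].
#' @export
subtract_blank <- function(sample, blank, grid_tol_nm = 1e-6) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (length(sample$wavelengths_nm) != length(blank$wavelengths_nm) ||
      any(abs(sample$wavelengths_nm - blank$wavelengths_nm) > grid_tol_nm)) {
    stop_grid("sample and blank are not on the same wavelength grid (tol %g nm)",
              grid_tol_nm)
  }
  out <- sample
  out$signal <- sample$signal - blank$signal
  if (out$kind %in% c("absorbance", "molar_absorptivity")) {
    out$signal <- pmax(out$signal, 0)  # blank can slightly exceed sample
  }
  out
}

#' Convert an absorbance spectrum to molar absorptivity
#'
#' Beer-Lambert scaling: epsilon(lambda) = A(lambda) / (c * l), giving
#' M^-1 cm^-1 when `concentration_M` is molar and `path_cm` centimetres.
#'
#' @param a an absorbance [spectrum()].
#' @param concentration_M chromophore concentration (M), > 0.
#' @param path_cm optical path length (cm), > 0.
#' @return A `molar_absorptivity` [spectrum()].
#' @export
absorbance_to_molar_absorptivity <- function(a, concentration_M, path_cm = 1) {
  stopifnot(inherits(a, "spectrum"))
  if (a$kind != "absorbance") stop_domain("input spectrum must have kind 'absorbance'")
  check_positive(concentration_M, "concentration_M")
  check_positive(path_cm, "path_cm")
  out <- a
  out$signal <- a$signal / (concentration_M * path_cm)
  out$kind <- "molar_absorptivity"
  out
}

## lambda_max by argmax with three-point parabolic refinement when the maximum
## is interior; a 1 nm grid otherwise quantises nm-scale band shifts.
locate_peak <- function(wl, sig) {
  i <- which.max(sig)
  n <- length(sig)
  if (i == 1L || i == n) return(list(lambda = wl[i], intensity = sig[i]))
  x <- wl[(i - 1L):(i + 1L)]; y <- sig[(i - 1L):(i + 1L)]
  p <- pracma::polyfit(x - x[2L], y, 2L)        # shifted for conditioning
  if (!is.finite(p[1L]) || p[1L] >= 0) return(list(lambda = wl[i], intensity = sig[i]))
  dx <- -p[2L] / (2 * p[1L])
  dx <- max(min(dx, x[3L] - x[2L]), x[1L] - x[2L])
  list(lambda = x[2L] + dx, intensity = pracma::polyval(p, dx))
}

#' Locate an emission/absorption peak and its shift against a reference
#'
#' Finds the band maximum of `sample` and `reference` inside `window_nm`
#' (grid argmax followed by three-point parabolic interpolation when the
#' maximum is interior) and reports the peak shift. Sign convention: negative
#' `shift_nm` means the sample peak moved to shorter wavelength (blue shift),
#' positive means red shift.
#'
#' @param sample,reference [spectrum()] objects.
#' @param window_nm optional `c(min, max)` wavelength window (nm); defaults to
#'   the overlap of the two grids.
#' @param refine logical; apply the parabolic refinement (default `TRUE`).
#' @return An object of class `"peak_report"` with fields `lambda_max_nm`,
#'   `intensity_at_max`, `reference_lambda_max_nm`, `shift_nm`,
#'   `intensity_ratio` and `sign_convention`.
#' @export
peak_report <- function(sample, reference, window_nm = NULL, refine = TRUE) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  lo <- max(min(sample$wavelengths_nm), min(reference$wavelengths_nm))
  hi <- min(max(sample$wavelengths_nm), max(reference$wavelengths_nm))
  if (!is.null(window_nm)) {
    lo <- max(lo, min(window_nm)); hi <- min(hi, max(window_nm))
  }
  if (lo >= hi) stop_window("peak window [%g, %g] nm has no overlap with both spectra", lo, hi)
  in_win <- function(sp) {
    keep <- sp$wavelengths_nm >= lo & sp$wavelengths_nm <= hi
    if (!any(keep)) stop_window("no grid points inside the peak window")
    list(wl = sp$wavelengths_nm[keep], sig = sp$signal[keep])
  }
  s <- in_win(sample); r <- in_win(reference)
  ps <- if (refine) locate_peak(s$wl, s$sig) else
    list(lambda = s$wl[which.max(s$sig)], intensity = max(s$sig))
  pr <- if (refine) locate_peak(r$wl, r$sig) else
    list(lambda = r$wl[which.max(r$sig)], intensity = max(r$sig))
  structure(
    list(lambda_max_nm = ps$lambda,
         intensity_at_max = ps$intensity,
         reference_lambda_max_nm = pr$lambda,
         reference_intensity_at_max = pr$intensity,
         shift_nm = ps$lambda - pr$lambda,
         intensity_ratio = ps$intensity / pr$intensity,
         sign_convention = "negative shift_nm = blue shift (toward shorter wavelength)"),
    class = "peak_report"
  )
}

#' @export
print.peak_report <- function(x, ...) {
  cat(sprintf("peak %.2f nm (reference %.2f nm): shift %+.2f nm, intensity ratio %.3f\n",
              x$lambda_max_nm, x$reference_lambda_max_nm, x$shift_nm, x$intensity_ratio))
  cat(" ", x$sign_convention, "\n")
  invisible(x)
}

#' Serialize a peak report to JSON
#'
#' @param report a [peak_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(report, path) {
  stopifnot(inherits(report, "peak_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hyperchromicity ratio at a wavelength
#'
#' Ratio of sample to reference signal at `lambda_nm` (linear interpolation
#' between grid points). A value above 1 indicates a hyperchromic shift —
#' increased absorption on complex formation.
#'
#' @param sample,reference [spectrum()] objects whose grids cover `lambda_nm`.
#' @param lambda_nm evaluation wavelength (nm).
#' @return A single numeric ratio.
#' @export
hyperchromicity <- function(sample, reference, lambda_nm) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  value_at <- function(sp) {
    if (lambda_nm < min(sp$wavelengths_nm) || lambda_nm > max(sp$wavelengths_nm)) {
      stop_window("%g nm lies outside the spectrum grid", lambda_nm)
    }
    approx(sp$wavelengths_nm, sp$signal, xout = lambda_nm)$y
  }
  s <- value_at(sample); r <- value_at(reference)
  if (r <= 0) stop_domain("reference signal at %g nm is not positive", lambda_nm)
  s / r
}
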