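# Forster resonance energy transfer: spectral overlap integral, Forster
# radius, transfer efficiency, donor-acceptor distance and the validity window.
#
# Unit dialect: the overlap integral J is assembled with lambda in nm and
# epsilon in M^-1 cm^-1, giving nm^4 M^-1 cm^-1; it is converted by 1e-28 to
# cm^3 M^-1 before entering the R0^6 prefactor (8.79e-25, which with J in
# cm^3 M^-1 yields R0 in cm). Both expressions of J are always returned.

#' FRET configuration
#'
#' @param kappa_squared dipole orientation factor; 2/3 for freely rotating
#'   dipoles (the default).
#' @param refractive_index refractive index of the medium; 1.336 for dilute
#'   aqueous buffer.
#' @param quantum_yield donor fluorescence quantum yield in the absence of
#'   acceptor; 0.15 for tryptophan in serum albumin.
#' @return A list of class `"fret_config"`.
#' @export
fret_config <- function(kappa_squared = 2 / 3, refractive_index = 1.336,
                        quantum_yield = 0.15) {
  if (!is_number(kappa_squared) || kappa_squared <= 0 || kappa_squared > 4) {
    stop_domain("kappa_squared must lie in (0, 4]")
  }
  if (!is_number(refractive_index) || refractive_index <= 1) {
    stop_domain("refractive_index must exceed 1")
  }
  if (!is_number(quantum_yield) || quantum_yield <= 0 || quantum_yield > 1) {
    stop_domain("quantum_yield must lie in (0, 1]")
  }
  structure(list(kappa_squared = kappa_squared,
                 refractive_index = refractive_index,
                 quantum_yield = quantum_yield),
            class = "fret_config")
}

#' Spectral overlap integral J
#'
#' `J = integral(F(lambda) eps(lambda) lambda^4 dlambda) / integral(F(lambda)
#' dlambda)` over `range_nm`, by composite trapezoid on the union of the two
#' wavelength grids restricted to the range (linear interpolation, never
#' extrapolation). `F` is the donor emission (arbitrary units, they cancel)
#' and `eps` the acceptor molar absorptivity (M^-1 cm^-1).
#'
#' @param donor_emission donor emission [spectrum()].
#' @param acceptor_epsilon acceptor [spectrum()] of kind `molar_absorptivity`
#'   (convert absorbance first with [absorbance_to_molar_absorptivity()]).
#' @param range_nm integration window `c(min, max)` in nm; default
#'   `c(300, 400)`, the usual tryptophan-donor window.
#' @return A list with `j_nm4_M_inv_cm_inv` (nm^4 M^-1 cm^-1), `j_cm3_M_inv`
#'   (cm^3 M^-1, factor 1e-28), `range_nm` and `n_grid`.
#' @export
overlap_integral <- function(donor_emission, acceptor_epsilon, range_nm = c(300, 400)) {
  stopifnot(inherits(donor_emission, "spectrum"), inherits(acceptor_epsilon, "spectrum"))
  if (acceptor_epsilon$kind != "molar_absorptivity") {
    stop_domain("acceptor spectrum must be in molar absorptivity units (kind 'molar_absorptivity')")
  }
  lo <- max(min(range_nm), min(donor_emission$wavelengths_nm),
            min(acceptor_epsilon$wavelengths_nm))
  hi <- min(max(range_nm), max(donor_emission$wavelengths_nm),
            max(acceptor_epsilon$wavelengths_nm))
  if (lo >= hi) stop_window("donor and acceptor grids do not overlap inside [%g, %g] nm",
                            min(range_nm), max(range_nm))
  grid <- sort(unique(c(donor_emission$wavelengths_nm, acceptor_epsilon$wavelengths_nm,
                        lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  f <- approx(donor_emission$wavelengths_nm, donor_emission$signal, xout = grid)$y
  eps <- approx(acceptor_epsilon$wavelengths_nm, acceptor_epsilon$signal, xout = grid)$y
  denom <- pracma::trapz(grid, f)
  if (denom <= 0) stop_domain("donor emission integrates to zero over the range")
  j <- pracma::trapz(grid, f * eps * grid^4) / denom
  list(j_nm4_M_inv_cm_inv = j,
       j_cm3_M_inv = j * 1e-28,
       range_nm = c(lo, hi),
       n_grid = length(grid))
}

#' Forster radius from the overlap integral
#'
#' `R0^6 = 8.79e-25 kappa^2 n^-4 phi J` with J in cm^3 M^-1 gives R0^6 in
#' cm^6; the radius is returned in nm.
#'
#' @param j overlap integral: either the list returned by
#'   [overlap_integral()] or a bare number in nm^4 M^-1 cm^-1.
#' @param config a [fret_config()].
#' @return Forster radius R0 in nm (the donor-acceptor distance at which the
#'   transfer efficiency is 50%).
#' @export
forster_radius <- function(j, config = fret_config()) {
  stopifnot(inherits(config, "fret_config"))
  j_cm3 <- if (is.list(j)) j$j_cm3_M_inv else if (is.numeric(j)) j * 1e-28 else
    stop_domain("j must be an overlap_integral() result or a number in nm^4 M^-1 cm^-1")
  if (j_cm3 < 0) stop_domain("overlap integral cannot be negative")
  r0_cm6 <- .FORSTER_PREFACTOR * config$kappa_squared *
    config$refractive_index^-4 * config$quantum_yield * j_cm3
  (r0_cm6^(1 / 6)) * 1e7
}

#' Transfer efficiency from donor intensities
#'
#' `E = 1 - F/F0`, with `F` and `F0` the donor intensity with and without the
#' acceptor (measured on the equimolar donor-acceptor pair).
#'
#' @param f donor intensity in the presence of the acceptor, `0 < f <= f0`.
#' @param f0 donor intensity without acceptor, > 0.
#' @return Efficiency in `[0, 1)`.
#' @export
efficiency_from_intensity <- function(f, f0) {
  if (!is_number(f) || !is_number(f0) || f0 <= 0 || f <= 0 || f > f0) {
    stop_domain("efficiency_from_intensity needs 0 < f <= f0")
  }
  1 - f / f0
}

#' Transfer efficiency at a donor-acceptor distance
#'
#' `E = R0^6 / (R0^6 + r^6)`.
#'
#' @param r_nm donor-acceptor distance (nm), >= 0.
#' @param r0_nm Forster radius (nm), > 0.
#' @return Efficiency in `(0, 1]`.
#' @export
efficiency_from_distance <- function(r_nm, r0_nm) {
  if (any(r_nm < 0)) stop_domain("distance must be >= 0")
  if (!is_number(r0_nm) || r0_nm <= 0) stop_domain("Forster radius must be > 0")
  r0_nm^6 / (r0_nm^6 + r_nm^6)
}

#' Donor-acceptor distance from the transfer efficiency
#'
#' Inverts `E = R0^6/(R0^6 + r^6)`: `r = R0 ((1 - E)/E)^(1/6)`.
#'
#' @param efficiency transfer efficiency, strictly between 0 and 1.
#' @param r0_nm Forster radius (nm), > 0.
#' @return Distance r in nm.
#' @export
distance_from_efficiency <- function(efficiency, r0_nm) {
  if (any(efficiency <= 0) || any(efficiency >= 1)) {
    stop_domain("efficiency must lie strictly between 0 and 1")
  }
  if (!is_number(r0_nm) || r0_nm <= 0) stop_domain("Forster radius must be > 0")
  r0_nm * ((1 - efficiency) / efficiency)^(1 / 6)
}

#' Forster validity window check
#'
#' Energy-transfer distance estimates are considered reliable only when
#' `0.5 R0 < r < 1.5 R0` (strict inequalities).
#'
#' @param r_nm donor-acceptor distance (nm), > 0.
#' @param r0_nm Forster radius (nm), > 0.
#' @return `TRUE` iff r lies strictly inside the window.
#' @export
forster_window_check <- function(r_nm, r0_nm) {
  if (any(r_nm <= 0) || !is_number(r0_nm) || r0_nm <= 0) {
    stop_domain("forster_window_check needs positive r and R0")
  }
  r_nm > 0.5 * r0_nm & r_nm < 1.5 * r0_nm
}

#' Full FRET analysis of a donor-acceptor pair
#'
#' Convenience composition: overlap integral, Forster radius, efficiency from
#' the measured intensity pair, distance, and the validity-window flag.
#'
#' @inheritParams overlap_integral
#' @param f,f0 donor intensity with and without acceptor (equimolar pair).
#' @param config a [fret_config()].
#' @return An object of class `"fret_result"` with fields
#'   `j_nm4_M_inv_cm_inv`, `j_cm3_M_inv`, `r0_nm`, `efficiency`, `r_nm`,
#'   `forster_window_ok`, and the configuration used.
#' @export
fret_analysis <- function(donor_emission, acceptor_epsilon, f, f0,
                          config = fret_config(), range_nm = c(300, 400)) {
  j <- overlap_integral(donor_emission, acceptor_epsilon, range_nm)
  r0 <- forster_radius(j, config)
  e <- efficiency_from_intensity(f, f0)
  r <- distance_from_efficiency(e, r0)
  structure(
    list(j_nm4_M_inv_cm_inv = j$j_nm4_M_inv_cm_inv,
         j_cm3_M_inv = j$j_cm3_M_inv,
         r0_nm = r0,
         efficiency = e,
         r_nm = r,
         forster_window_ok = forster_window_check(r, r0),
         config = config,
         range_nm = j$range_nm),
    class = "fret_result"
  )
}

#' @export
print.fret_result <- function(x, ...) {
  cat("FRET analysis\n")
  cat(sprintf("  J  = %.4g nm^4 M^-1 cm^-1 (= %.4g cm^3 M^-1)\n",
              x$j_nm4_M_inv_cm_inv, x$j_cm3_M_inv))
  cat(sprintf("  R0 = %.3f nm   E = %.3f   r = %.3f nm\n", x$r0_nm, x$efficiency, x$r_nm))
  cat(sprintf("  0.5 R0 < r < 1.5 R0: %s\n", x$forster_window_ok))
  invisible(x)
}
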