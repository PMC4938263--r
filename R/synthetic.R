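# Synthetic-data generators with known ground truth. Static quenching is
# generated through the non-fluorescent ground-state-complex model
# F = F0 / (1 + Kb [Q]^n), so the double-log Stern-Volmer transform is exact
# by construction; every estimator in the package can therefore be checked
# against the generating parameters.

#' Ground truth for a synthetic binding study
#'
#' Default values describe a tight single-site static quencher of a 5 uM
#' serum-albumin solution titrated 0-50 uM: Kb = 3.14e5 M^-1, n = 1.1,
#' exothermic binding (dH = -15.806 kcal/mol) with dS fixed so that
#' Kb(298 K) equals the stated Kb, a tryptophan emission band at 340 nm that
#' blue-shifts to 326 nm when bound, and noise-free readout.
#'
#' @param kb_M_inv binding constant at the reference temperature (M^-1).
#' @param n_sites apparent number of binding sites.
#' @param ksv_M_inv optional collisional Stern-Volmer constant for
#'   pure-collisional scenarios; defaults to `kb_M_inv` (static quenching).
#' @param delta_h_kcal_mol,delta_s_cal_mol_K van't Hoff ground truth for
#'   temperature series; the default dS (-27.89051 cal mol^-1 K^-1) makes
#'   Kb(298 K) = 3.14e5 M^-1 under the default dH.
#' @param band_center_free_nm,band_center_bound_nm emission band maxima of the
#'   free and bound protein (bound must not exceed free: binding blue-shifts).
#' @param band_sigma_nm Gaussian bandwidth (nm).
#' @param f0_peak unquenched peak intensity (a.u.).
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   photometric noise on F, in `[0, 0.2)`.
#' @param seed integer seed; all generators are pure functions of
#'   (parameters, seed).
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth <- function(kb_M_inv = 3.14e5, n_sites = 1.1, ksv_M_inv = NULL,
                         delta_h_kcal_mol = -15.806,
                         delta_s_cal_mol_K = -27.89051,
                         band_center_free_nm = 340, band_center_bound_nm = 326,
                         band_sigma_nm = 15, f0_peak = 1000,
                         noise_cv = 0, seed = 1L) {
  check_positive(kb_M_inv, "kb_M_inv")
  check_positive(n_sites, "n_sites")
  check_positive(band_sigma_nm, "band_sigma_nm")
  check_positive(f0_peak, "f0_peak")
  if (!is_number(noise_cv) || noise_cv < 0 || noise_cv >= 0.2) {
    stop_domain("noise_cv must lie in [0, 0.2)")
  }
  if (band_center_bound_nm > band_center_free_nm) {
    stop_domain("bound band center must not exceed the free one (binding blue-shifts)")
  }
  structure(
    list(kb_M_inv = kb_M_inv, n_sites = n_sites,
         ksv_M_inv = ksv_M_inv %||% kb_M_inv,
         delta_h_kcal_mol = delta_h_kcal_mol,
         delta_s_cal_mol_K = delta_s_cal_mol_K,
         band_center_free_nm = band_center_free_nm,
         band_center_bound_nm = band_center_bound_nm,
         band_sigma_nm = band_sigma_nm,
         f0_peak = f0_peak, noise_cv = noise_cv, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Generate a static-quenching titration
#'
#' Emits `F = F0 / (1 + Kb [Q]^n)` on the concentration grid, with optional
#' multiplicative Gaussian noise (`truth$noise_cv`) on the quenched points.
#' When `spectra = TRUE` each point also gets a Gaussian emission band whose
#' center interpolates linearly from the free to the bound position with the
#' bound fraction `Kb [Q]^n / (1 + Kb [Q]^n)`, reproducing the blue shift of
#' the tryptophan band on binding.
#'
#' @param truth a [ground_truth()].
#' @param q_grid_M quencher concentration grid (M), ascending, starting at 0;
#'   default 0-50 uM in 5 uM steps (a 1:0 to 1:10 titration of 5 uM protein).
#' @param temperature_K temperature stamped on the series; default 298 K.
#' @param spectra also emit per-point emission spectra (default `FALSE`).
#' @param protein_label,marker_label metadata for the series.
#' @return A [titration_series()]; when `spectra = TRUE` it carries a
#'   `spectra` element (list of [spectrum()], one per point).
#' @export
generate_titration <- function(truth, q_grid_M = seq(0, 50e-6, by = 5e-6),
                               temperature_K = 298, spectra = FALSE,
                               protein_label = "synthetic", marker_label = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (q_grid_M[1L] != 0 || any(diff(q_grid_M) <= 0)) {
    stop_domain("q_grid_M must be ascending and start at 0")
  }
  q <- as.numeric(q_grid_M)
  kbqn <- truth$kb_M_inv * ifelse(q > 0, q^truth$n_sites, 0)
  f <- truth$f0_peak / (1 + kbqn)
  if (truth$noise_cv > 0) {
    noise <- withr::with_seed(truth$seed, stats::rnorm(length(q), 1, truth$noise_cv))
    idx <- q > 0
    f[idx] <- f[idx] * pmax(noise[idx], 0.05)  # keep intensities positive
  }
  series <- titration_series(q, f, f0 = truth$f0_peak,
                             protein_label = protein_label,
                             protein_conc_M = 5e-6,
                             temperature_K = temperature_K,
                             marker_label = marker_label)
  if (spectra) {
    theta <- kbqn / (1 + kbqn)  # bound fraction
    centers <- truth$band_center_free_nm +
      theta * (truth$band_center_bound_nm - truth$band_center_free_nm)
    wl <- seq(truth$band_center_bound_nm - 5 * truth$band_sigma_nm,
              truth$band_center_free_nm + 5 * truth$band_sigma_nm, by = 1)
    series$spectra <- lapply(seq_along(q), function(i) {
      spectrum(wl, f[i] * exp(-(wl - centers[i])^2 / (2 * truth$band_sigma_nm^2)),
               kind = "emission",
               meta = list(label = sprintf("[Q] = %.3g M", q[i]),
                           temperature_K = temperature_K))
    })
  }
  series
}

#' Generate a multi-temperature titration series from van't Hoff ground truth
#'
#' `Kb(T) = exp(-dH/(R T) + dS/R)` with the truth's dH (kcal/mol) and dS
#' (cal mol^-1 K^-1), then one titration per temperature (seeds offset per
#' temperature so replicates are independent but reproducible).
#'
#' @param truth a [ground_truth()].
#' @param temps_K distinct temperatures (K); default `c(298, 303, 310)`.
#' @inheritParams generate_titration
#' @return A list with one element per temperature: `temperature_K`,
#'   `kb_true_M_inv`, `series`.
#' @export
generate_temperature_series <- function(truth, temps_K = c(298, 303, 310),
                                        q_grid_M = seq(0, 50e-6, by = 5e-6),
                                        protein_label = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  if (anyDuplicated(temps_K)) stop_domain("temperatures must be distinct")
  lapply(seq_along(temps_K), function(i) {
    t_k <- temps_K[i]
    kb_t <- kb_from_thermo(truth$delta_h_kcal_mol, truth$delta_s_cal_mol_K, t_k)
    truth_t <- truth
    truth_t$kb_M_inv <- kb_t
    truth_t$seed <- truth$seed + i
    list(temperature_K = t_k,
         kb_true_M_inv = kb_t,
         series = generate_titration(truth_t, q_grid_M, temperature_K = t_k,
                                     protein_label = protein_label))
  })
}

#' Generate a Gaussian donor-emission / acceptor-absorptivity pair
#'
#' Two Gaussian bands sampled on a shared grid covering +/- 5 sigma of both,
#' plus the overlap integral of the same analytic bands evaluated by fine
#' quadrature (0.01 nm trapezoid on the closed-form Gaussians) as an
#' independent oracle for the grid-based implementation.
#'
#' @param donor_center_nm,donor_sigma_nm donor emission band (nm).
#' @param acceptor_center_nm,acceptor_sigma_nm acceptor absorptivity band (nm).
#' @param epsilon_peak acceptor peak molar absorptivity (M^-1 cm^-1).
#' @param grid_step_nm sampling step of the emitted spectra (nm), default 1.
#' @param donor_peak donor peak intensity (a.u., cancels in J), default 1000.
#' @return A list `donor` ([spectrum()]), `acceptor` ([spectrum()], molar
#'   absorptivity), `analytic_j_nm4_M_inv_cm_inv`, `range_nm`.
#' @export
generate_overlap_pair <- function(donor_center_nm = 340, donor_sigma_nm = 15,
                                  acceptor_center_nm = 330, acceptor_sigma_nm = 12,
                                  epsilon_peak = 4000, grid_step_nm = 1,
                                  donor_peak = 1000) {
  check_positive(donor_sigma_nm, "donor_sigma_nm")
  check_positive(acceptor_sigma_nm, "acceptor_sigma_nm")
  check_positive(epsilon_peak, "epsilon_peak")
  check_positive(grid_step_nm, "grid_step_nm")
  lo <- min(donor_center_nm - 5 * donor_sigma_nm, acceptor_center_nm - 5 * acceptor_sigma_nm)
  hi <- max(donor_center_nm + 5 * donor_sigma_nm, acceptor_center_nm + 5 * acceptor_sigma_nm)
  f_of <- function(x) donor_peak * exp(-(x - donor_center_nm)^2 / (2 * donor_sigma_nm^2))
  e_of <- function(x) epsilon_peak * exp(-(x - acceptor_center_nm)^2 / (2 * acceptor_sigma_nm^2))
  grid <- seq(lo, hi, by = grid_step_nm)
  fine <- seq(lo, hi, by = 0.01)
  analytic_j <- pracma::trapz(fine, f_of(fine) * e_of(fine) * fine^4) /
    pracma::trapz(fine, f_of(fine))
  list(donor = spectrum(grid, f_of(grid), kind = "emission",
                        meta = list(label = "synthetic donor emission")),
       acceptor = spectrum(grid, e_of(grid), kind = "molar_absorptivity",
                           meta = list(label = "synthetic acceptor absorptivity")),
       analytic_j_nm4_M_inv_cm_inv = analytic_j,
       range_nm = c(lo, hi))
}

#' Generate a site-marker displacement dataset
#'
#' One marker-free titration plus one titration per marker with the effective
#' quenching constant scaled by the marker's competition factor in `(0, 1]`
#' (1 = no competition). All series share the truth's `n_sites`; because the
#' least-squares slope is linear in the response, the fitted Stern-Volmer
#' constant then scales exactly by the factor and the fractional decrease
#' recovered by [displacement_analysis()] equals `1 - factor`.
#'
#' @param truth a [ground_truth()]; `truth$ksv_M_inv` is the marker-free
#'   constant.
#' @param marker_factors named numeric vector of factors in `(0, 1]`, e.g.
#'   `c(DIA = 0.125, PBZ = 0.24, WAR = 0.34)`.
#' @inheritParams generate_titration
#' @return Named list of [titration_series()]: element `"free"` plus one per
#'   marker.
#' @export
generate_displacement_set <- function(truth, marker_factors,
                                      q_grid_M = seq(0, 50e-6, by = 5e-6),
                                      temperature_K = 298,
                                      protein_label = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  if (!length(marker_factors) || is.null(names(marker_factors))) {
    stop_domain("marker_factors must be a named numeric vector")
  }
  if (any(marker_factors <= 0) || any(marker_factors > 1)) {
    stop_domain("marker factors must lie in (0, 1]")
  }
  make <- function(factor, label, offset) {
    t <- truth
    t$kb_M_inv <- truth$ksv_M_inv * factor
    t$seed <- truth$seed + offset
    generate_titration(t, q_grid_M, temperature_K = temperature_K,
                       protein_label = protein_label,
                       marker_label = if (identical(label, "free")) NULL else label)
  }
  out <- c(list(free = make(1, "free", 0L)),
           lapply(seq_along(marker_factors), function(i) {
             make(marker_factors[i], names(marker_factors)[i], i)
           }))
  names(out) <- c("free", names(marker_factors))
  out
}
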