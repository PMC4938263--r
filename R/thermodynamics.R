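# Binding thermodynamics: Gibbs free energy from the binding constant,
# van't Hoff enthalpy/entropy from a multi-temperature Kb series, and
# interaction-force classification from the signs of dH and dS.

#' Gibbs free energy of binding
#'
#' `dG = -R T ln(Kb)`, returned in kcal/mol. Natural logarithm; the gas
#' constant defaults to 1.987 cal mol^-1 K^-1.
#'
#' @param kb_M_inv binding constant (M^-1), > 0.
#' @param temperature_K absolute temperature (K), > 0.
#' @param r_cal_mol_K gas constant in cal mol^-1 K^-1.
#' @return Free energy change in kcal/mol (negative for favourable binding).
#' @export
delta_g <- function(kb_M_inv, temperature_K, r_cal_mol_K = .R_CAL) {
  if (any(kb_M_inv <= 0) || any(temperature_K <= 0)) {
    stop_domain("delta_g needs kb > 0 and temperature > 0")
  }
  check_positive(r_cal_mol_K, "r_cal_mol_K")
  -r_cal_mol_K * temperature_K * log(kb_M_inv) / 1000
}

#' Binding constant implied by van't Hoff parameters
#'
#' Inverts the integrated van't Hoff relation
#' `ln Kb = -dH/(R T) + dS/R` (constant dH, dS).
#'
#' @param delta_h_kcal_mol enthalpy change (kcal/mol).
#' @param delta_s_cal_mol_K entropy change (cal mol^-1 K^-1).
#' @param temperature_K absolute temperature (K).
#' @param r_cal_mol_K gas constant in cal mol^-1 K^-1.
#' @return Binding constant (M^-1).
#' @export
kb_from_thermo <- function(delta_h_kcal_mol, delta_s_cal_mol_K, temperature_K,
                           r_cal_mol_K = .R_CAL) {
  if (any(temperature_K <= 0)) stop_domain("temperature must be > 0")
  exp(-delta_h_kcal_mol * 1000 / (r_cal_mol_K * temperature_K) +
        delta_s_cal_mol_K / r_cal_mol_K)
}

#' Van't Hoff fit of a multi-temperature binding-constant series
#'
#' Unweighted ordinary least squares of `ln(Kb)` against `1/T`. The slope is
#' `-dH/R` and the intercept `dS/R`, assuming temperature-independent dH and
#' dS over the (narrow) range studied. Per temperature the result also carries
#' `dG = -R T ln(Kb)` and `T dS = dH - dG`; the entropic term is reported both
#' as `dS` (cal mol^-1 K^-1, from the intercept) and as `TdS` (kcal/mol) since
#' published tables frequently mix the two up.
#'
#' @param temperature_K temperatures (K), at least 2 distinct values.
#' @param kb_M_inv binding constants (M^-1), all > 0, same length.
#' @param r_cal_mol_K gas constant in cal mol^-1 K^-1.
#' @param force_threshold_kcal_mol passed to [classify_forces()].
#' @return An object of class `"thermo_result"`: `table` (data frame with
#'   `temperature_K`, `kb_M_inv`, `delta_g_kcal_mol`, `t_delta_s_kcal_mol`),
#'   `delta_h_kcal_mol`, `delta_s_cal_mol_K`, `vant_hoff_slope_K`,
#'   `vant_hoff_intercept`, `r_squared`, `r_cal_mol_K`, `force_call`.
#' @export
vant_hoff_fit <- function(temperature_K, kb_M_inv, r_cal_mol_K = .R_CAL,
                          force_threshold_kcal_mol = 1) {
  if (length(temperature_K) != length(kb_M_inv)) {
    stop_format("temperature_K and kb_M_inv must have the same length")
  }
  if (any(kb_M_inv <= 0) || any(temperature_K <= 0)) {
    stop_domain("van't Hoff fit needs kb > 0 and temperature > 0")
  }
  if (length(unique(temperature_K)) < 2L) {
    stop_insufficient("van't Hoff fit needs >= 2 distinct temperatures")
  }
  x <- 1 / temperature_K
  y <- log(kb_M_inv)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])       # K; equals -dH/R
  intercept <- unname(coef(fit)[1L])   # dimensionless; equals dS/R
  dh <- -r_cal_mol_K * slope / 1000    # kcal/mol
  ds <- r_cal_mol_K * intercept        # cal mol^-1 K^-1
  ord <- order(temperature_K)
  dg <- delta_g(kb_M_inv[ord], temperature_K[ord], r_cal_mol_K)
  structure(
    list(table = data.frame(temperature_K = temperature_K[ord],
                            kb_M_inv = kb_M_inv[ord],
                            delta_g_kcal_mol = dg,
                            t_delta_s_kcal_mol = dh - dg),
         delta_h_kcal_mol = dh,
         delta_s_cal_mol_K = ds,
         vant_hoff_slope_K = slope,
         vant_hoff_intercept = intercept,
         r_squared = r_squared_of(fit),
         r_cal_mol_K = r_cal_mol_K,
         force_call = classify_forces(dh, ds, force_threshold_kcal_mol)),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("van't Hoff analysis\n")
  cat(sprintf("  dH = %.3f kcal/mol   dS = %.3f cal/(mol K)   R^2 = %s\n",
              x$delta_h_kcal_mol, x$delta_s_cal_mol_K,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  for (i in seq_len(nrow(x$table))) {
    with(x$table[i, ], cat(sprintf("  %g K: Kb = %.4g M^-1, dG = %.3f kcal/mol, TdS = %.3f kcal/mol\n",
                                   temperature_K, kb_M_inv, delta_g_kcal_mol,
                                   t_delta_s_kcal_mol)))
  }
  cat("  dominant forces:", x$force_call, "\n")
  invisible(x)
}

#' Classify the dominant binding forces from dH and dS signs
#'
#' The empirical sign rules for protein-ligand association: dH < 0 with
#' dS < 0 indicates hydrogen bonding and van der Waals contacts; dH > 0 with
#' dS > 0 indicates hydrophobic interactions; dH near zero with dS > 0
#' indicates electrostatic/ionic interactions. Other sign patterns are
#' reported as mixed/indeterminate.
#'
#' @param delta_h_kcal_mol enthalpy change (kcal/mol).
#' @param delta_s_cal_mol_K entropy change (cal mol^-1 K^-1).
#' @param dh_zero_threshold_kcal_mol magnitude below which dH counts as
#'   "approximately zero" for the ionic rule; default 1 kcal/mol.
#' @return One of `"hydrogen bonding / van der Waals"`, `"hydrophobic"`,
#'   `"electrostatic/ionic"`, `"mixed/indeterminate"`.
#' @export
classify_forces <- function(delta_h_kcal_mol, delta_s_cal_mol_K,
                            dh_zero_threshold_kcal_mol = 1) {
  dh <- delta_h_kcal_mol; ds <- delta_s_cal_mol_K
  if (!is_number(dh) || !is_number(ds)) stop_domain("dH and dS must be single numbers")
  if (abs(dh) <= dh_zero_threshold_kcal_mol && ds > 0) {
    "electrostatic/ionic"
  } else if (dh < 0 && ds < 0) {
    "hydrogen bonding / van der Waals"
  } else if (dh > 0 && ds > 0) {
    "hydrophobic"
  } else {
    "mixed/indeterminate"
  }
}
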