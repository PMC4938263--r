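# Stokes-Einstein hydrodynamic sizing: diffusion coefficient <-> hydrodynamic
# radius, a built-in water-viscosity helper, and condition-to-condition size
# change reports.

#' Dynamic viscosity of water
#'
#' Standard Vogel-type correlation `eta(T) = 2.414e-5 * 10^(247.8/(T - 140))`
#' Pa s, accurate to well under 1% between 273 and 373 K (8.937e-4 Pa s at
#' 298 K). Used as the default solvent viscosity when none is supplied.
#'
#' @param temperature_K absolute temperature (K), in `[273, 373]`.
#' @return Viscosity in Pa s.
#' @export
water_viscosity_Pa_s <- function(temperature_K) {
  if (any(temperature_K < 273) || any(temperature_K > 373)) {
    stop_domain("water viscosity correlation is valid for 273-373 K")
  }
  2.414e-5 * 10^(247.8 / (temperature_K - 140))
}

#' Hydrodynamic radius from the diffusion coefficient (Stokes-Einstein)
#'
#' `Rh = kB T / (6 pi eta D)` with `kB = 1.380649e-23` J/K. All inputs SI;
#' the radius is returned in nm.
#'
#' @param diffusion_m2_s translational diffusion coefficient (m^2/s), > 0.
#' @param temperature_K absolute temperature (K), > 0.
#' @param viscosity_Pa_s solvent viscosity (Pa s); defaults to water at
#'   `temperature_K` via [water_viscosity_Pa_s()].
#' @return Hydrodynamic radius in nm.
#' @export
stokes_einstein_radius <- function(diffusion_m2_s, temperature_K,
                                   viscosity_Pa_s = water_viscosity_Pa_s(temperature_K)) {
  if (any(diffusion_m2_s <= 0) || any(temperature_K <= 0) || any(viscosity_Pa_s <= 0)) {
    stop_domain("stokes_einstein_radius needs positive D, T and viscosity")
  }
  .KB_SI * temperature_K / (6 * pi * viscosity_Pa_s * diffusion_m2_s) * 1e9
}

#' Diffusion coefficient from the hydrodynamic radius
#'
#' Inverse of [stokes_einstein_radius()]: `D = kB T / (6 pi eta Rh)`.
#'
#' @param rh_nm hydrodynamic radius (nm), > 0.
#' @inheritParams stokes_einstein_radius
#' @return Diffusion coefficient in m^2/s.
#' @export
diffusion_from_radius <- function(rh_nm, temperature_K,
                                  viscosity_Pa_s = water_viscosity_Pa_s(temperature_K)) {
  if (any(rh_nm <= 0) || any(temperature_K <= 0) || any(viscosity_Pa_s <= 0)) {
    stop_domain("diffusion_from_radius needs positive Rh, T and viscosity")
  }
  .KB_SI * temperature_K / (6 * pi * viscosity_Pa_s * rh_nm * 1e-9)
}

#' Condition-to-condition hydrodynamic size change report
#'
#' Compares each condition's hydrodynamic radius against the ligand-free
#' baseline of the same protein and calls the direction of change. A decrease
#' beyond `threshold` (fractional) is called `"compaction"`, an increase
#' beyond it `"expansion/aggregation"`, anything smaller `"no change"` —
#' changes below instrument polydispersity are not interpreted.
#'
#' @param measurements data frame with columns `protein`, `condition` (e.g.
#'   the protein:ligand molar ratio, `"1:0"`, `"1:5"`, `"1:10"`), `rh_nm`,
#'   and optionally `polydispersity_pct`. Alternatively supply
#'   `diffusion_m2_s` plus `temperature_K` (and optionally `viscosity_Pa_s`)
#'   instead of `rh_nm`, and radii are computed via [stokes_einstein_radius()].
#' @param baseline_condition condition label of the ligand-free measurement,
#'   default `"1:0"`.
#' @param threshold fractional change below which no direction is called;
#'   default 0.05.
#' @return An object of class `"size_change_report"`: a data frame with
#'   `rh_nm`, `pct_change` (vs baseline) and `direction` per row.
#' @export
size_change_report <- function(measurements, baseline_condition = "1:0",
                               threshold = 0.05) {
  m <- as.data.frame(measurements)
  if (!all(c("protein", "condition") %in% names(m))) {
    stop_config("measurements need `protein` and `condition` columns")
  }
  if (!"rh_nm" %in% names(m)) {
    if (!all(c("diffusion_m2_s", "temperature_K") %in% names(m))) {
      stop_config("supply either `rh_nm` or `diffusion_m2_s` + `temperature_K`")
    }
    eta <- if ("viscosity_Pa_s" %in% names(m)) m$viscosity_Pa_s else
      water_viscosity_Pa_s(m$temperature_K)
    m$rh_nm <- stokes_einstein_radius(m$diffusion_m2_s, m$temperature_K, eta)
  }
  if (any(m$rh_nm <= 0)) stop_domain("hydrodynamic radii must be positive")
  out <- lapply(split(m, m$protein), function(g) {
    base <- g$rh_nm[g$condition == baseline_condition]
    if (length(base) != 1L) {
      stop_config("protein %s needs exactly one ligand-free baseline condition '%s'",
                  g$protein[1L], baseline_condition)
    }
    g$pct_change <- 100 * (g$rh_nm - base) / base
    g$direction <- ifelse(g$condition == baseline_condition, "baseline",
                          ifelse(g$pct_change < -100 * threshold, "compaction",
                                 ifelse(g$pct_change > 100 * threshold,
                                        "expansion/aggregation", "no change")))
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("size_change_report", "data.frame")
  out
}

#' @export
print.size_change_report <- function(x, ...) {
  cat("hydrodynamic size changes (vs ligand-free baseline)\n")
  print.data.frame(x[, intersect(c("protein", "condition", "rh_nm", "pct_change",
                                   "direction", "polydispersity_pct"), names(x))],
                   digits = 4, row.names = FALSE)
  invisible(x)
}
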