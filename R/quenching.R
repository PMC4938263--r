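# Fluorescence quenching titrations: Stern-Volmer and modified (double-log)
# Stern-Volmer fits, quenching-mechanism classification, and site-marker
# competitive displacement analysis.

#' Construct a fluorescence quenching titration series
#'
#' Fluorescence readout of a fixed protein concentration titrated with a
#' quencher (the ligand) at one temperature. `f0` is the unquenched intensity;
#' if omitted it is taken from the `[Q] = 0` row, which must then be present.
#'
#' @param quencher_conc_M quencher concentrations (M), non-negative, strictly
#'   increasing.
#' @param fluorescence intensities (a.u.), all > 0, same length.
#' @param f0 unquenched intensity at `[Q] = 0`; defaults to the intensity of
#'   the `[Q] = 0` point.
#' @param protein_label,protein_conc_M,temperature_K,marker_label metadata;
#'   `marker_label` names a site marker co-incubated with the protein (e.g.
#'   `"WAR"`, `"PBZ"`, `"DIA"`), `NULL` for the marker-free series.
#' @return An object of class `"titration_series"` whose `points` element is a
#'   data frame with columns `quencher_conc_M` and `fluorescence`.
#' @export
titration_series <- function(quencher_conc_M, fluorescence, f0 = NULL,
                             protein_label = "protein", protein_conc_M = NA_real_,
                             temperature_K = NA_real_, marker_label = NULL) {
  if (length(quencher_conc_M) != length(fluorescence)) {
    stop_format("quencher_conc_M and fluorescence must have the same length")
  }
  if (any(quencher_conc_M < 0)) stop_domain("quencher concentrations must be >= 0")
  if (any(diff(quencher_conc_M) <= 0)) {
    stop_domain("quencher concentrations must be strictly increasing")
  }
  if (any(fluorescence <= 0)) stop_domain("all fluorescence intensities must be > 0")
  has_zero <- quencher_conc_M[1L] == 0
  if (is.null(f0)) {
    if (!has_zero) stop_domain("f0 missing and no [Q] = 0 point to take it from")
    f0 <- fluorescence[1L]
  }
  check_positive(f0, "f0")
  if (has_zero && abs(fluorescence[1L] - f0) > 1e-9 * f0) {
    stop_domain("the [Q] = 0 point must carry the unquenched intensity f0")
  }
  structure(
    list(points = data.frame(quencher_conc_M = as.numeric(quencher_conc_M),
                             fluorescence = as.numeric(fluorescence)),
         f0 = f0,
         protein_label = protein_label,
         protein_conc_M = protein_conc_M,
         temperature_K = temperature_K,
         marker_label = marker_label),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration: %s%s, %d points, [Q] %.3g-%.3g M%s>\n",
              x$protein_label,
              if (!is.null(x$marker_label)) paste0(" + ", x$marker_label) else "",
              nrow(x$points), min(x$points$quencher_conc_M),
              max(x$points$quencher_conc_M),
              if (is.finite(x$temperature_K)) sprintf(", %g K", x$temperature_K) else ""))
  invisible(x)
}

#' Read a titration table from a delimited text file
#'
#' Expects two numeric columns, quencher concentration (M) and fluorescence,
#' with comma/tab/whitespace separation and at most one header line.
#'
#' @param path file path.
#' @inheritParams titration_series
#' @return A [titration_series()].
#' @export
read_titration <- function(path, f0 = NULL, protein_label = "protein",
                           protein_conc_M = NA_real_, temperature_K = NA_real_,
                           marker_label = NULL) {
  if (!file.exists(path)) stop_format("titration file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_row <- function(line) suppressWarnings(as.numeric(split_fields(line)[1:2]))
  first <- parse_row(lines[1L])
  start <- if (anyNA(first)) 2L else 1L
  rows <- lapply(seq(start, length(lines)), function(i) {
    v <- parse_row(lines[i])
    if (anyNA(v)) stop_format("%s: non-numeric data on line %d: '%s'", path, i, lines[i])
    v
  })
  m <- do.call(rbind, rows)
  titration_series(m[, 1L], m[, 2L], f0 = f0, protein_label = protein_label,
                   protein_conc_M = protein_conc_M, temperature_K = temperature_K,
                   marker_label = marker_label)
}

#' Write a titration table to a delimited text file
#'
#' @param x a [titration_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(x, path) {
  stopifnot(inherits(x, "titration_series"))
  writeLines(c("quencher_conc_M,fluorescence",
               paste(formatC(x$points$quencher_conc_M, digits = 15, format = "g"),
                     formatC(x$points$fluorescence, digits = 15, format = "g"),
                     sep = ",")), path)
  invisible(path)
}

#' Stern-Volmer fit of a quenching titration
#'
#' Ordinary least squares of `F0/F` against `[Q]` with a free intercept:
#' `F0/F = Ksv [Q] + 1`. The slope is the Stern-Volmer constant `Ksv` (M^-1)
#' and `kq = Ksv / tau0` is the bimolecular quenching rate constant. The
#' intercept is reported rather than forced to 1; a warning is raised when it
#' departs from 1 by more than 0.1, which usually signals a blank-subtraction
#' or normalisation problem.
#'
#' @param series a [titration_series()].
#' @param tau0_s fluorophore excited-state lifetime (s); tryptophan in serum
#'   albumin is ~1e-9 s, the default.
#' @return An object of class `"quenching_fit"` with fields `ksv_M_inv`,
#'   `intercept`, `intercept_flagged`, `kq_M_inv_s_inv`, `tau0_s`, `r_squared`,
#'   `n_points_used`, plus the series metadata.
#' @export
stern_volmer_fit <- function(series, tau0_s = 1e-9) {
  stopifnot(inherits(series, "titration_series"))
  check_positive(tau0_s, "tau0_s")
  pts <- series$points
  use <- pts$quencher_conc_M > 0
  if (sum(use) < 3L) {
    stop_insufficient("Stern-Volmer fit needs >= 3 points with [Q] > 0 (got %d)", sum(use))
  }
  x <- pts$quencher_conc_M[use]
  y <- series$f0 / pts$fluorescence[use]
  fit <- lm(y ~ x)
  ksv <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  flagged <- abs(intercept - 1) > 0.1
  if (flagged) {
    warning(sprintf("Stern-Volmer intercept %.3f departs from 1 by more than 0.1; check blank subtraction", intercept))
  }
  structure(
    list(ksv_M_inv = ksv,
         intercept = intercept,
         intercept_flagged = flagged,
         kq_M_inv_s_inv = ksv / tau0_s,
         tau0_s = tau0_s,
         r_squared = r_squared_of(fit),
         n_points_used = sum(use),
         protein_label = series$protein_label,
         temperature_K = series$temperature_K,
         marker_label = series$marker_label),
    class = "quenching_fit"
  )
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%s%s%s)\n", x$protein_label,
              if (is.finite(x$temperature_K)) sprintf(", %g K", x$temperature_K) else "",
              if (!is.null(x$marker_label)) paste0(", + ", x$marker_label) else ""))
  cat(sprintf("  Ksv = %.4g M^-1   intercept = %.4f%s\n", x$ksv_M_inv, x$intercept,
              if (x$intercept_flagged) " [flagged]" else ""))
  cat(sprintf("  kq  = %.4g M^-1 s^-1 (tau0 = %.3g s)   R^2 = %s   n = %d\n",
              x$kq_M_inv_s_inv, x$tau0_s,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$n_points_used))
  invisible(x)
}

#' Modified Stern-Volmer (double-logarithmic) binding fit
#'
#' Ordinary least squares of `log10(F0/F - 1)` against `log10([Q])`:
#' the intercept is `log10(Kb)` (binding constant) and the slope is `n`, the
#' apparent number of binding sites. Base-10 logarithms throughout. Points
#' where `F0/F - 1 <= 0` (no measurable quenching; the logarithm is undefined)
#' are excluded and their row indices recorded in `excluded_points`.
#'
#' @param series a [titration_series()].
#' @return An object of class `"binding_fit"` with fields `kb_M_inv`,
#'   `n_sites`, `log10_kb`, `r_squared`, `n_points_used`, `excluded_points`.
#' @export
modified_sv_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  ratio <- series$f0 / pts$fluorescence - 1
  positive_q <- pts$quencher_conc_M > 0
  usable <- positive_q & ratio > 0
  excluded <- which(positive_q & ratio <= 0)
  if (sum(usable) < 3L) {
    stop_insufficient("modified Stern-Volmer fit needs >= 3 usable points (got %d after excluding %d)",
                      sum(usable), length(excluded))
  }
  x <- log10(pts$quencher_conc_M[usable])
  y <- log10(ratio[usable])
  fit <- lm(y ~ x)
  log10_kb <- unname(coef(fit)[1L])
  n_sites <- unname(coef(fit)[2L])
  if (n_sites <= 0) {
    warning("fitted number of binding sites is not positive; the series does not follow the binding model")
  }
  structure(
    list(kb_M_inv = 10^log10_kb,
         n_sites = n_sites,
         log10_kb = log10_kb,
         r_squared = r_squared_of(fit),
         n_points_used = sum(usable),
         excluded_points = excluded,
         protein_label = series$protein_label,
         temperature_K = series$temperature_K,
         marker_label = series$marker_label),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("modified Stern-Volmer fit (%s%s)\n", x$protein_label,
              if (is.finite(x$temperature_K)) sprintf(", %g K", x$temperature_K) else ""))
  cat(sprintf("  Kb = %.4g M^-1 (log10 Kb = %.4f)   n = %.4f   R^2 = %s   n_points = %d\n",
              x$kb_M_inv, x$log10_kb, x$n_sites,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$n_points_used))
  if (length(x$excluded_points)) {
    cat("  excluded points (F0/F - 1 <= 0):", paste(x$excluded_points, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Static quenching (ground-state complex formation) weakens on heating, so
#' `Ksv` falls with temperature, and its apparent `kq` exceeds the maximum
#' diffusion-controlled rate (~2e10 M^-1 s^-1). Dynamic (collisional)
#' quenching shows the opposite trend with `kq` below that limit. The call is
#' `"static"` only when the `Ksv` trend is strictly decreasing AND every `kq`
#' exceeds the diffusion limit; `"dynamic"` only on the strict converse;
#' anything else is `"ambiguous"`.
#'
#' @param fits list of [stern_volmer_fit()] results at two or more distinct
#'   temperatures (any order; sorted internally).
#' @param diffusion_limit_M_inv_s_inv diffusion-controlled ceiling for
#'   biopolymer quenching, default `2.0e10` M^-1 s^-1.
#' @return An object of class `"mechanism_call"` with fields `call`,
#'   `ksv_temperature_trend`, `kq_exceeds_diffusion_limit`,
#'   `diffusion_limit_M_inv_s_inv`, `temperatures_K`, `ksv_M_inv`, `kq_M_inv_s_inv`.
#' @export
classify_mechanism <- function(fits, diffusion_limit_M_inv_s_inv = .DIFFUSION_LIMIT) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop_insufficient("mechanism classification needs fits at >= 2 temperatures")
  }
  lapply(fits, function(f) stopifnot(inherits(f, "quenching_fit")))
  temps <- vapply(fits, `[[`, numeric(1), "temperature_K")
  if (anyNA(temps)) stop_domain("every fit must carry its temperature_K")
  if (anyDuplicated(temps)) stop_domain("duplicate temperatures in mechanism classification")
  ord <- order(temps)
  ksv <- vapply(fits, `[[`, numeric(1), "ksv_M_inv")[ord]
  kq <- vapply(fits, `[[`, numeric(1), "kq_M_inv_s_inv")[ord]
  d <- diff(ksv)
  trend <- if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing" else "flat"
  exceeds <- all(kq > diffusion_limit_M_inv_s_inv)
  call <- if (trend == "decreasing" && exceeds) "static"
          else if (trend == "increasing" && !exceeds) "dynamic"
          else "ambiguous"
  structure(
    list(call = call,
         ksv_temperature_trend = trend,
         kq_exceeds_diffusion_limit = exceeds,
         diffusion_limit_M_inv_s_inv = diffusion_limit_M_inv_s_inv,
         temperatures_K = temps[ord],
         ksv_M_inv = ksv,
         kq_M_inv_s_inv = kq),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("quenching mechanism: %s (Ksv %s with T; kq %s the %.2g M^-1 s^-1 diffusion limit)\n",
              x$call, x$ksv_temperature_trend,
              if (x$kq_exceeds_diffusion_limit) "all exceed" else "do not all exceed",
              x$diffusion_limit_M_inv_s_inv))
  invisible(x)
}

#' Site-marker competitive displacement analysis
#'
#' Compares the Stern-Volmer constant of the marker-free titration with the
#' constants obtained with each site marker pre-bound. A large fractional
#' decrease `1 - Ksv_with / Ksv_free` means the marker and the ligand compete
#' for the same cavity; the primary site call is the Sudlow site of the marker
#' with the largest decrease. Markers whose decrease exceeds
#' `secondary_threshold` but are not primary are flagged as secondary sites.
#'
#' @param free marker-free [stern_volmer_fit()] (or a bare `Ksv` number).
#' @param with_markers named list of fits (or `Ksv` numbers), one per marker.
#' @param site_map named character vector mapping each marker label to a site,
#'   e.g. `c(WAR = "site I", PBZ = "site I", DIA = "site II")`.
#' @param secondary_threshold fractional decrease above which a non-primary
#'   marker's site is still flagged as a (secondary) binding site; default 0.5.
#' @return An object of class `"displacement_report"` with fields
#'   `ksv_free_M_inv`, `markers` (data frame: `marker`, `site`,
#'   `ksv_with_marker_M_inv`, `fractional_decrease`), `primary_site_call`,
#'   `primary_marker`, `secondary_sites`.
#' @export
displacement_analysis <- function(free, with_markers, site_map,
                                  secondary_threshold = 0.5) {
  get_ksv <- function(x) {
    if (inherits(x, "quenching_fit")) x$ksv_M_inv
    else if (is_number(x)) x
    else stop_domain("expected a quenching_fit or a single Ksv value")
  }
  ksv_free <- get_ksv(free)
  check_positive(ksv_free, "ksv_free")
  if (!length(with_markers)) stop_insufficient("displacement analysis needs at least one marker series")
  labels <- names(with_markers)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop_config("with_markers must be a named list of marker fits")
  }
  missing <- setdiff(labels, names(site_map))
  if (length(missing)) {
    stop_config("marker(s) missing from site_map: %s", paste(missing, collapse = ", "))
  }
  ksv_with <- vapply(with_markers, get_ksv, numeric(1))
  frac <- 1 - ksv_with / ksv_free
  markers <- data.frame(marker = labels,
                        site = unname(site_map[labels]),
                        ksv_with_marker_M_inv = unname(ksv_with),
                        fractional_decrease = unname(frac),
                        stringsAsFactors = FALSE)
  if (all(frac <= 0)) {
    primary_marker <- NA_character_
    primary_site <- "none"
  } else {
    primary_marker <- labels[which.max(frac)]
    primary_site <- unname(site_map[primary_marker])
  }
  secondary <- unique(markers$site[markers$fractional_decrease > secondary_threshold &
                                     markers$marker != primary_marker])
  secondary <- setdiff(secondary, primary_site)
  structure(
    list(ksv_free_M_inv = ksv_free,
         markers = markers,
         primary_site_call = primary_site,
         primary_marker = primary_marker,
         secondary_sites = secondary,
         secondary_threshold = secondary_threshold),
    class = "displacement_report"
  )
}

#' @export
print.displacement_report <- function(x, ...) {
  cat(sprintf("site-marker displacement (Ksv free = %.4g M^-1)\n", x$ksv_free_M_inv))
  for (i in seq_len(nrow(x$markers))) {
    with(x$markers[i, ], cat(sprintf("  %-4s (%s): Ksv = %.4g M^-1, decrease %.1f%%\n",
                                     marker, site, ksv_with_marker_M_inv,
                                     100 * fractional_decrease)))
  }
  cat(sprintf("  primary binding site: %s%s\n", x$primary_site_call,
              if (length(x$secondary_sites))
                paste0(" (secondary: ", paste(x$secondary_sites, collapse = ", "), ")")
              else ""))
  invisible(x)
}
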