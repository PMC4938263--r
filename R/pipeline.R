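# Study driver: one declarative YAML configuration in, one structured report
# out. Stages (quenching/thermodynamics per protein, displacement, FRET,
# hydrodynamic sizing) are all optional; every numeric quantity in the report
# carries an explicit unit string.

qty <- function(value, unit) list(value = value, unit = unit)

default_constants <- function(constants = NULL) {
  defaults <- list(tau0_s = 1e-9,
                   r_cal_mol_K = .R_CAL,
                   kappa_squared = 2 / 3,
                   quantum_yield = 0.15,
                   refractive_index = 1.336,
                   diffusion_limit_M_inv_s_inv = .DIFFUSION_LIMIT,
                   secondary_site_threshold = 0.5,
                   compaction_threshold = 0.05)
  utils::modifyList(defaults, constants %||% list())
}

#' Run a full binding study from a configuration
#'
#' Executes the pipeline — titration fits per temperature, mechanism
#' classification, van't Hoff thermodynamics, site-marker displacement, FRET
#' and hydrodynamic sizing — according to a declarative configuration, and
#' returns one structured report. Any stage may be absent from the
#' configuration. All referenced files are checked before any computation.
#'
#' The configuration (YAML file or equivalent list) has top-level keys
#' `seed`, `constants` (tau0_s, r_cal_mol_K, kappa_squared, quantum_yield,
#' refractive_index, diffusion_limit_M_inv_s_inv, secondary_site_threshold,
#' compaction_threshold — all optional, defaults echoed into the report),
#' `proteins` (list of `label`, `protein_conc_M`, `titrations` = list of
#' `{temperature_K, path}`, optional `markers` = list of
#' `{label, site, path}`), `fret` (`donor_path`, `acceptor_path`,
#' `acceptor_kind` = `"absorbance"` or `"molar_absorptivity"`,
#' `acceptor_conc_M`, `path_cm`, `f`, `f0`, `range_nm`) and `hydro`
#' (`path` to a delimited table with columns `protein`, `condition`, `rh_nm`
#' and optionally `polydispersity_pct`; `baseline_condition`).
#'
#' @param config path to a YAML configuration file, or the equivalent list.
#' @param base_dir directory against which relative paths in the config are
#'   resolved; defaults to the config file's directory.
#' @return An object of class `"study_report"` (nested list, JSON-ready).
#' @export
run_study <- function(config, base_dir = NULL) {
  config_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    if (!file.exists(config_path)) stop_config("config file not found: %s", config_path)
    base_dir <- base_dir %||% dirname(config_path)
    config <- yaml::read_yaml(config_path)
  }
  base_dir <- base_dir %||% "."
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)

  ## fail fast: every referenced file must exist before any computation
  paths <- character(0)
  for (pr in config$proteins %||% list()) {
    paths <- c(paths,
               vapply(pr$titrations %||% list(), function(t) resolve(t$path), character(1)),
               vapply(pr$markers %||% list(), function(m) resolve(m$path), character(1)))
  }
  if (!is.null(config$fret)) {
    paths <- c(paths, resolve(config$fret$donor_path), resolve(config$fret$acceptor_path))
  }
  if (!is.null(config$hydro)) paths <- c(paths, resolve(config$hydro$path))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_config("missing input file(s): %s", paste(missing, collapse = ", "))
  }

  constants <- default_constants(config$constants)
  report <- list(
    provenance = list(
      package = "specbind",
      package_version = as.character(utils::packageVersion("specbind")),
      seed = config$seed %||% NA,
      config_md5 = if (!is.null(config_path)) unname(tools::md5sum(config_path)) else NA,
      input_md5 = as.list(setNames(unname(tools::md5sum(paths)), basename(paths))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    constants = list(
      tau0_s = qty(constants$tau0_s, "s"),
      r_cal_mol_K = qty(constants$r_cal_mol_K, "cal mol^-1 K^-1"),
      kappa_squared = qty(constants$kappa_squared, "1"),
      quantum_yield = qty(constants$quantum_yield, "1"),
      refractive_index = qty(constants$refractive_index, "1"),
      diffusion_limit_M_inv_s_inv = qty(constants$diffusion_limit_M_inv_s_inv, "M^-1 s^-1"),
      secondary_site_threshold = qty(constants$secondary_site_threshold, "1"),
      compaction_threshold = qty(constants$compaction_threshold, "1")
    )
  )

  if (length(config$proteins %||% list())) {
    report$proteins <- lapply(config$proteins, function(pr) {
      run_protein_stage(pr, constants, resolve)
    })
    names(report$proteins) <- vapply(config$proteins, `[[`, character(1), "label")
  }

  if (!is.null(config$fret)) {
    fr <- config$fret
    donor <- read_spectrum(resolve(fr$donor_path), kind = "emission")
    acceptor_kind <- fr$acceptor_kind %||% "absorbance"
    acceptor <- read_spectrum(resolve(fr$acceptor_path), kind = acceptor_kind)
    if (acceptor_kind == "absorbance") {
      acceptor <- absorbance_to_molar_absorptivity(acceptor, fr$acceptor_conc_M,
                                                   fr$path_cm %||% 1)
    }
    cfg <- fret_config(constants$kappa_squared, constants$refractive_index,
                       constants$quantum_yield)
    res <- fret_analysis(donor, acceptor, fr$f, fr$f0, config = cfg,
                         range_nm = unlist(fr$range_nm %||% c(300, 400)))
    report$fret <- list(
      j_nm4_M_inv_cm_inv = qty(res$j_nm4_M_inv_cm_inv, "nm^4 M^-1 cm^-1"),
      j_cm3_M_inv = qty(res$j_cm3_M_inv, "cm^3 M^-1"),
      r0_nm = qty(res$r0_nm, "nm"),
      efficiency = qty(res$efficiency, "1"),
      r_nm = qty(res$r_nm, "nm"),
      forster_window_ok = res$forster_window_ok,
      range_nm = qty(res$range_nm, "nm")
    )
  }

  if (!is.null(config$hydro)) {
    tab <- utils::read.table(resolve(config$hydro$path), header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
    rep_h <- size_change_report(tab,
                                baseline_condition = config$hydro$baseline_condition %||% "1:0",
                                threshold = constants$compaction_threshold)
    report$hydro <- lapply(seq_len(nrow(rep_h)), function(i) {
      row <- rep_h[i, ]
      out <- list(protein = row$protein, condition = row$condition,
                  rh_nm = qty(row$rh_nm, "nm"),
                  pct_change = qty(row$pct_change, "%"),
                  direction = row$direction)
      if ("polydispersity_pct" %in% names(row)) {
        out$polydispersity_pct <- qty(row$polydispersity_pct, "%")
      }
      out
    })
  }

  structure(report, class = "study_report")
}

run_protein_stage <- function(pr, constants, resolve) {
  label <- pr$label %||% "protein"
  titr <- pr$titrations %||% list()
  temps <- vapply(titr, function(t) as.numeric(t$temperature_K), numeric(1))
  if (anyDuplicated(temps)) stop_config("%s: duplicate titration temperatures", label)
  fits_sv <- list(); fits_msv <- list(); binding <- list()
  for (i in seq_along(titr)) {
    series <- read_titration(resolve(titr[[i]]$path), protein_label = label,
                             protein_conc_M = pr$protein_conc_M %||% NA_real_,
                             temperature_K = temps[i])
    sv <- stern_volmer_fit(series, tau0_s = constants$tau0_s)
    msv <- modified_sv_fit(series)
    fits_sv[[i]] <- sv; fits_msv[[i]] <- msv
    binding[[i]] <- list(
      temperature_K = qty(temps[i], "K"),
      ksv_M_inv = qty(sv$ksv_M_inv, "M^-1"),
      sv_intercept = qty(sv$intercept, "1"),
      kq_M_inv_s_inv = qty(sv$kq_M_inv_s_inv, "M^-1 s^-1"),
      sv_r_squared = qty(sv$r_squared, "1"),
      kb_M_inv = qty(msv$kb_M_inv, "M^-1"),
      n_sites = qty(msv$n_sites, "1"),
      msv_r_squared = qty(msv$r_squared, "1"),
      delta_g_kcal_mol = qty(delta_g(msv$kb_M_inv, temps[i], constants$r_cal_mol_K),
                             "kcal mol^-1")
    )
  }
  out <- list(label = label, binding = binding)

  if (length(fits_sv) >= 2L) {
    mech <- classify_mechanism(fits_sv, constants$diffusion_limit_M_inv_s_inv)
    out$mechanism <- list(call = mech$call,
                          ksv_temperature_trend = mech$ksv_temperature_trend,
                          kq_exceeds_diffusion_limit = mech$kq_exceeds_diffusion_limit,
                          diffusion_limit_M_inv_s_inv =
                            qty(mech$diffusion_limit_M_inv_s_inv, "M^-1 s^-1"))
    th <- vant_hoff_fit(temps, vapply(fits_msv, `[[`, numeric(1), "kb_M_inv"),
                        r_cal_mol_K = constants$r_cal_mol_K)
    out$thermo <- list(
      delta_h_kcal_mol = qty(th$delta_h_kcal_mol, "kcal mol^-1"),
      delta_s_cal_mol_K = qty(th$delta_s_cal_mol_K, "cal mol^-1 K^-1"),
      r_squared = qty(th$r_squared, "1"),
      force_call = th$force_call,
      per_temperature = lapply(seq_len(nrow(th$table)), function(i) {
        row <- th$table[i, ]
        list(temperature_K = qty(row$temperature_K, "K"),
             kb_M_inv = qty(row$kb_M_inv, "M^-1"),
             delta_g_kcal_mol = qty(row$delta_g_kcal_mol, "kcal mol^-1"),
             t_delta_s_kcal_mol = qty(row$t_delta_s_kcal_mol, "kcal mol^-1"))
      })
    )
  }

  markers <- pr$markers %||% list()
  if (length(markers)) {
    if (!length(fits_sv)) stop_config("%s: markers need a marker-free titration", label)
    marker_fits <- lapply(markers, function(m) {
      series <- read_titration(resolve(m$path), protein_label = label,
                               temperature_K = as.numeric(m$temperature_K %||% temps[1L]),
                               marker_label = m$label)
      stern_volmer_fit(series, tau0_s = constants$tau0_s)
    })
    names(marker_fits) <- vapply(markers, `[[`, character(1), "label")
    site_map <- setNames(vapply(markers, `[[`, character(1), "site"),
                         names(marker_fits))
    disp <- displacement_analysis(fits_sv[[1L]], marker_fits, site_map,
                                  secondary_threshold = constants$secondary_site_threshold)
    out$displacement <- list(
      ksv_free_M_inv = qty(disp$ksv_free_M_inv, "M^-1"),
      markers = lapply(seq_len(nrow(disp$markers)), function(i) {
        row <- disp$markers[i, ]
        list(marker = row$marker, site = row$site,
             ksv_with_marker_M_inv = qty(row$ksv_with_marker_M_inv, "M^-1"),
             fractional_decrease = qty(row$fractional_decrease, "1"))
      }),
      primary_site_call = disp$primary_site_call,
      primary_marker = disp$primary_marker,
      secondary_sites = disp$secondary_sites
    )
  }
  out
}

#' Write a study report to JSON
#'
#' @param report a [run_study()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Validate a study report's unit discipline
#'
#' Walks the report and checks that every numeric leaf outside the provenance
#' block is wrapped as `{value, unit}` with a non-empty unit string.
#'
#' @param report a [run_study()] result (or equivalent list).
#' @return `TRUE`, invisibly; otherwise an error naming the offending field.
#' @export
validate_study_report <- function(report) {
  walk <- function(x, path) {
    if (is.list(x)) {
      if (!is.null(x$unit) || !is.null(x$value)) {
        if (is.null(x$value) || is.null(x$unit) ||
            !is.numeric(x$value) || !is.character(x$unit) || !nzchar(x$unit)) {
          stop_config("malformed quantity at %s: need numeric `value` + unit string", path)
        }
        return(invisible(NULL))
      }
      nms <- names(x) %||% seq_along(x)
      for (i in seq_along(x)) walk(x[[i]], paste0(path, "/", nms[i]))
    } else if (is.numeric(x) && !is.logical(x)) {
      stop_config("unit-less numeric field at %s", path)
    }
    invisible(NULL)
  }
  body <- unclass(report)
  body$provenance <- NULL
  walk(body, "")
  invisible(TRUE)
}

#' Render a study report as delimited text tables
#'
#' Emits tab-separated blocks in the conventional layout of binding-study
#' papers: one binding/thermodynamics table (protein, temperature, n, Ksv,
#' kq, Kb, dH, dG, TdS), one site-marker displacement table, one FRET table
#' and one hydrodynamics table — whichever stages the report contains.
#'
#' @param report a [run_study()] result.
#' @return A character vector of lines, invisibly; also printed when
#'   `print = TRUE`.
#' @param print print the tables to the console (default `FALSE`).
#' @export
render_tables <- function(report, print = FALSE) {
  stopifnot(inherits(report, "study_report"))
  v <- function(x) if (is.null(x)) NA_real_ else x$value
  lines <- character(0)
  tsv <- function(...) paste(..., sep = "\t")

  if (!is.null(report$proteins)) {
    lines <- c(lines, "# Binding and thermodynamic parameters",
               tsv("protein", "temperature_K", "n", "Ksv_M_inv", "kq_M_inv_s_inv",
                   "Kb_M_inv", "dH_kcal_mol", "dG_kcal_mol", "TdS_kcal_mol"))
    for (pr in report$proteins) {
      th <- pr$thermo
      for (i in seq_along(pr$binding)) {
        b <- pr$binding[[i]]
        tds <- if (!is.null(th)) v(th$per_temperature[[i]]$t_delta_s_kcal_mol) else NA_real_
        lines <- c(lines, tsv(pr$label,
                              format(v(b$temperature_K)),
                              signif(v(b$n_sites), 4),
                              signif(v(b$ksv_M_inv), 4),
                              signif(v(b$kq_M_inv_s_inv), 4),
                              signif(v(b$kb_M_inv), 4),
                              if (!is.null(th)) signif(v(th$delta_h_kcal_mol), 5) else NA,
                              signif(v(b$delta_g_kcal_mol), 4),
                              if (!is.null(th)) signif(tds, 4) else NA))
      }
    }
    disp_rows <- Filter(function(pr) !is.null(pr$displacement), report$proteins)
    if (length(disp_rows)) {
      lines <- c(lines, "", "# Site-marker displacement",
                 tsv("protein", "marker", "site", "Ksv_with_marker_M_inv",
                     "fractional_decrease", "primary_site_call"))
      for (pr in disp_rows) {
        for (m in pr$displacement$markers) {
          lines <- c(lines, tsv(pr$label, m$marker, m$site,
                                signif(v(m$ksv_with_marker_M_inv), 4),
                                signif(v(m$fractional_decrease), 4),
                                pr$displacement$primary_site_call))
        }
      }
    }
  }

  if (!is.null(report$fret)) {
    fr <- report$fret
    lines <- c(lines, "", "# FRET parameters",
               tsv("J_nm4_M_inv_cm_inv", "J_cm3_M_inv", "R0_nm", "r_nm",
                   "E_FRET", "forster_window_ok"),
               tsv(signif(v(fr$j_nm4_M_inv_cm_inv), 4), signif(v(fr$j_cm3_M_inv), 4),
                   signif(v(fr$r0_nm), 4), signif(v(fr$r_nm), 4),
                   signif(v(fr$efficiency), 4), fr$forster_window_ok))
  }

  if (!is.null(report$hydro)) {
    lines <- c(lines, "", "# Hydrodynamic radii",
               tsv("protein", "condition", "Rh_nm", "pct_change", "direction"))
    for (row in report$hydro) {
      lines <- c(lines, tsv(row$protein, row$condition, signif(v(row$rh_nm), 4),
                            signif(v(row$pct_change), 4), row$direction))
    }
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  render_tables(x, print = TRUE)
  invisible(x)
}

#' Simulate a complete synthetic binding study on disk
#'
#' Writes a self-contained study directory — titration tables at three
#' temperatures, site-marker titrations, a donor-emission/acceptor-absorbance
#' spectrum pair, a hydrodynamic-radius table, a YAML configuration wiring
#' them together, and a `manifest.yaml` recording the generating ground truth
#' (the oracle for end-to-end tests). The hydrodynamic radii are synthetic
#' fixtures emulating ligand-induced compaction; all other files follow the
#' generating models exactly (up to `truth$noise_cv`).
#'
#' @param dir output directory (created if needed).
#' @param truth a [ground_truth()].
#' @param temps_K titration temperatures, default `c(298, 303, 310)`.
#' @param marker_factors named competition factors for
#'   [generate_displacement_set()]; names must be assigned to Sudlow sites in
#'   `marker_sites`.
#' @param marker_sites named site assignment for each marker.
#' @param seed optional seed overriding `truth$seed`.
#' @return The path to the written configuration file, invisibly.
#' @export
simulate_study <- function(dir, truth = ground_truth(),
                           temps_K = c(298, 303, 310),
                           marker_factors = c(DIA = 0.125, PBZ = 0.24, WAR = 0.34),
                           marker_sites = c(DIA = "site II", PBZ = "site I", WAR = "site I"),
                           seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(seed)) truth$seed <- as.integer(seed)
  if (!all(names(marker_factors) %in% names(marker_sites))) {
    stop_config("every marker factor needs a site assignment in marker_sites")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  temp_series <- generate_temperature_series(truth, temps_K, protein_label = "SYN")
  titr_cfg <- lapply(temp_series, function(ts) {
    path <- sprintf("titration_%gK.csv", ts$temperature_K)
    write_titration(ts$series, file.path(dir, path))
    list(temperature_K = ts$temperature_K, path = path)
  })

  disp <- generate_displacement_set(truth, marker_factors, temperature_K = temps_K[1L],
                                    protein_label = "SYN")
  marker_cfg <- lapply(names(marker_factors), function(lab) {
    path <- sprintf("marker_%s.csv", lab)
    write_titration(disp[[lab]], file.path(dir, path))
    list(label = lab, site = unname(marker_sites[lab]), path = path)
  })

  pair <- generate_overlap_pair(donor_center_nm = truth$band_center_free_nm,
                                donor_sigma_nm = truth$band_sigma_nm)
  write_spectrum(pair$donor, file.path(dir, "donor_emission.csv"))
  ## manifest oracle: 0.01 nm quadrature of the analytic bands over the
  ## integration window the study configuration prescribes
  fret_range <- c(300, 400)
  pair_fine <- generate_overlap_pair(donor_center_nm = truth$band_center_free_nm,
                                     donor_sigma_nm = truth$band_sigma_nm,
                                     grid_step_nm = 0.01)
  j_oracle <- overlap_integral(pair_fine$donor, pair_fine$acceptor,
                               range_nm = fret_range)$j_nm4_M_inv_cm_inv
  acceptor_conc <- 5e-6
  absorbance <- pair$acceptor
  absorbance$signal <- absorbance$signal * acceptor_conc * 1
  absorbance$kind <- "absorbance"
  write_spectrum(absorbance, file.path(dir, "acceptor_absorbance.csv"))
  ## equimolar-point donor intensity from the generating quenching law
  f_ratio <- 1 / (1 + truth$kb_M_inv * acceptor_conc^truth$n_sites)

  hydro <- data.frame(protein = "SYN", condition = c("1:0", "1:5", "1:10"),
                      rh_nm = c(3.6, 3.0, 2.7), polydispersity_pct = c(11.0, 11.9, 12.5))
  utils::write.csv(hydro, file.path(dir, "hydro.csv"), row.names = FALSE, quote = FALSE)

  config <- list(
    seed = truth$seed,
    constants = default_constants(),
    proteins = list(list(label = "SYN", protein_conc_M = 5e-6,
                         titrations = titr_cfg, markers = marker_cfg)),
    fret = list(donor_path = "donor_emission.csv",
                acceptor_path = "acceptor_absorbance.csv",
                acceptor_kind = "absorbance",
                acceptor_conc_M = acceptor_conc, path_cm = 1,
                f = truth$f0_peak * f_ratio, f0 = truth$f0_peak,
                range_nm = fret_range),
    hydro = list(path = "hydro.csv", baseline_condition = "1:0")
  )
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)

  manifest <- list(
    ground_truth = unclass(truth),
    kb_per_temperature = setNames(
      lapply(temp_series, function(ts) ts$kb_true_M_inv),
      sprintf("T%g", vapply(temp_series, `[[`, numeric(1), "temperature_K"))),
    marker_factors = as.list(marker_factors),
    marker_sites = as.list(marker_sites),
    analytic_j_nm4_M_inv_cm_inv = j_oracle,
    fret_f_over_f0 = f_ratio,
    hydro_synthetic = TRUE
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(config_path)
}
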