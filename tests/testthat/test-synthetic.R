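test_that("generators are pure functions of parameters and seed", {
  tr <- ground_truth(noise_cv = 0.05, seed = 99)
  a <- generate_titration(tr); b <- generate_titration(tr)
  expect_identical(a$points, b$points)
  tr2 <- tr; tr2$seed <- 100L
  expect_false(identical(generate_titration(tr2)$points$fluorescence,
                         a$points$fluorescence))
})

test_that("noiseless titrations invert through both quenching estimators", {
  tr <- ground_truth(kb_M_inv = 3.14e5, n_sites = 1.1, noise_cv = 0)
  fit <- modified_sv_fit(generate_titration(tr))
  expect_equal(fit$kb_M_inv, 3.14e5, tolerance = 1e-9)
  expect_equal(fit$n_sites, 1.1, tolerance = 1e-9)

  ## with n = 1 the generating law reduces to F0/F = 1 + K[Q] exactly
  tr1 <- ground_truth(kb_M_inv = 5.03e4, n_sites = 1, noise_cv = 0)
  s <- generate_titration(tr1)
  q <- s$points$quencher_conc_M
  expect_equal(s$f0 / s$points$fluorescence, 1 + 5.03e4 * q, tolerance = 1e-12)
  expect_equal(stern_volmer_fit(s)$ksv_M_inv, 5.03e4, tolerance = 1e-9)
})

test_that("titration generation validates its grid and ground truth", {
  tr <- ground_truth()
  expect_error(generate_titration(tr, q_grid_M = c(5e-6, 10e-6)),
               class = "specbind_domain_error")  # must start at 0
  expect_error(ground_truth(noise_cv = 0.5), class = "specbind_domain_error")
  expect_error(ground_truth(band_center_free_nm = 326, band_center_bound_nm = 340),
               class = "specbind_domain_error")
})

test_that("per-point emission spectra reproduce the binding blue shift", {
  tr <- ground_truth(noise_cv = 0)
  s <- generate_titration(tr, spectra = TRUE)
  expect_length(s$spectra, nrow(s$points))
  shift <- peak_report(s$spectra[[length(s$spectra)]], s$spectra[[1]])$shift_nm
  expect_lt(shift, 0)  # blue shift grows with the bound fraction
  theta_last <- with(tr, kb_M_inv * max(s$points$quencher_conc_M)^n_sites /
                       (1 + kb_M_inv * max(s$points$quencher_conc_M)^n_sites))
  expect_equal(shift, theta_last * (326 - 340), tolerance = 0.05)
})

test_that("temperature series follow the van't Hoff law and invert end-to-end", {
  tr <- ground_truth(noise_cv = 0)
  ts <- generate_temperature_series(tr)
  temps <- vapply(ts, `[[`, numeric(1), "temperature_K")
  kb_true <- vapply(ts, `[[`, numeric(1), "kb_true_M_inv")
  ## exothermic truth: Kb strictly decreasing with temperature
  expect_true(all(diff(kb_true) < 0))
  expect_equal(kb_true[1], 3.14e5, tolerance = 1e-3)  # dS default pins Kb(298)

  kb_fit <- vapply(ts, function(x) modified_sv_fit(x$series)$kb_M_inv, numeric(1))
  th <- vant_hoff_fit(temps, kb_fit)
  expect_equal(th$delta_h_kcal_mol, tr$delta_h_kcal_mol, tolerance = 1e-3)
  expect_equal(th$delta_s_cal_mol_K, tr$delta_s_cal_mol_K, tolerance = 1e-3)

  flat <- ground_truth(delta_h_kcal_mol = 0, delta_s_cal_mol_K = 20, noise_cv = 0)
  ts_flat <- generate_temperature_series(flat)
  expect_equal(ts_flat[[1]]$kb_true_M_inv, ts_flat[[3]]$kb_true_M_inv, tolerance = 1e-12)

  expect_error(generate_temperature_series(tr, temps_K = c(298, 298)),
               class = "specbind_domain_error")
})

test_that("overlap pairs carry a usable fine-quadrature oracle", {
  pair <- generate_overlap_pair()
  j <- overlap_integral(pair$donor, pair$acceptor, pair$range_nm)
  expect_equal(j$j_nm4_M_inv_cm_inv, pair$analytic_j_nm4_M_inv_cm_inv, tolerance = 5e-4)

  ## widely separated bands overlap to essentially nothing
  far <- generate_overlap_pair(donor_center_nm = 340, donor_sigma_nm = 1,
                               acceptor_center_nm = 420, acceptor_sigma_nm = 1)
  j_far <- overlap_integral(far$donor, far$acceptor, far$range_nm)
  scale <- 4000 * 340^4  # magnitude of a fully-overlapped J for these bands
  expect_lt(j_far$j_nm4_M_inv_cm_inv / scale, 1e-10)
  expect_lt(far$analytic_j_nm4_M_inv_cm_inv / scale, 1e-10)

  ## refinement brings the sampled J closer to the oracle
  coarse <- generate_overlap_pair(grid_step_nm = 2)
  halved <- generate_overlap_pair(grid_step_nm = 1)
  err <- function(p) abs(overlap_integral(p$donor, p$acceptor, c(310, 370))$j_nm4_M_inv_cm_inv -
                           overlap_integral(generate_overlap_pair(grid_step_nm = 0.01)$donor,
                                            generate_overlap_pair(grid_step_nm = 0.01)$acceptor,
                                            c(310, 370))$j_nm4_M_inv_cm_inv)
  expect_lt(err(halved), err(coarse))
})

test_that("displacement sets reproduce competitive-binding calls", {
  tr <- ground_truth(ksv_M_inv = 5.03e4, n_sites = 1, noise_cv = 0)
  factors <- c(DIA = 0.125, PBZ = 0.24, WAR = 0.34)
  set <- generate_displacement_set(tr, factors)
  expect_named(set, c("free", "DIA", "PBZ", "WAR"))
  fits <- lapply(set[-1], stern_volmer_fit)
  rep <- displacement_analysis(stern_volmer_fit(set$free), fits, albumin_site_map)
  expect_identical(rep$primary_site_call, "site II")
  expect_equal(rep$markers$fractional_decrease[rep$markers$marker == "DIA"],
               1 - 0.125, tolerance = 1e-6)

  ## slope linearity: the fitted Ksv scales exactly by the factor even when
  ## the generating law is superlinear (n = 1.1)
  tr11 <- ground_truth(ksv_M_inv = 5.03e4, n_sites = 1.1, noise_cv = 0)
  set11 <- generate_displacement_set(tr11, c(DIA = 0.125))
  rep11 <- suppressWarnings(
    displacement_analysis(stern_volmer_fit(set11$free),
                          list(DIA = stern_volmer_fit(set11$DIA)), albumin_site_map))
  expect_equal(rep11$markers$fractional_decrease, 1 - 0.125, tolerance = 1e-9)

  null_set <- generate_displacement_set(tr, c(DIA = 1, WAR = 1))
  null_rep <- displacement_analysis(stern_volmer_fit(null_set$free),
                                    lapply(null_set[-1], stern_volmer_fit),
                                    albumin_site_map)
  expect_identical(null_rep$primary_site_call, "none")

  single <- generate_displacement_set(tr, c(WAR = 0.1))
  single_rep <- displacement_analysis(stern_volmer_fit(single$free),
                                      lapply(single[-1], stern_volmer_fit),
                                      albumin_site_map)
  expect_identical(single_rep$primary_marker, "WAR")

  expect_error(generate_displacement_set(tr, c(DIA = 1.5)),
               class = "specbind_domain_error")
  expect_error(generate_displacement_set(tr, c(DIA = 0)),
               class = "specbind_domain_error")
})
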