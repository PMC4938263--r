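test_that("Stern-Volmer fit recovers the generating constant exactly", {
  ## noiseless series built from the HSA 298 K quenching constant
  s <- make_static_series(5.03e4, n = 1)
  fit <- stern_volmer_fit(s)
  expect_equal(fit$ksv_M_inv, 5.03e4, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_false(fit$intercept_flagged)
  expect_equal(fit$kq_M_inv_s_inv, 5.03e13, tolerance = 1e-12)
  expect_equal(fit$n_points_used, 10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  ## agrees with the independent normal-equations oracle
  q <- s$points$quencher_conc_M[-1]
  o <- ols_oracle(q, s$f0 / s$points$fluorescence[-1])
  expect_equal(fit$ksv_M_inv, unname(o["slope"]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-9)
})

test_that("degenerate and undersized titrations are handled", {
  q <- seq(5e-6, 50e-6, by = 5e-6)
  flat <- titration_series(c(0, q), rep(1000, 11))
  expect_equal(stern_volmer_fit(flat)$ksv_M_inv, 0, tolerance = 1e-9)

  two <- titration_series(c(0, 5e-6, 10e-6), c(1000, 900, 800))
  expect_error(stern_volmer_fit(two), class = "specbind_insufficient_data_error")
  expect_error(titration_series(c(0, 1e-6), c(1000, -5)), class = "specbind_domain_error")
  expect_error(titration_series(c(0, 2e-6, 1e-6), c(1000, 1, 2)),
               class = "specbind_domain_error")
})

test_that("an off-unity intercept is reported and flagged, not hidden", {
  q <- seq(5e-6, 50e-6, by = 5e-6)
  ## un-subtracted background inflates every F0/F reading
  f <- 1000 / (1 + 5e4 * q)
  s <- titration_series(q, f * 0.8, f0 = 1000)
  expect_warning(fit <- stern_volmer_fit(s), "intercept")
  expect_true(fit$intercept_flagged)
  expect_gt(abs(fit$intercept - 1), 0.1)
})

test_that("kq/Ksv is exactly 1/tau0 across randomized fits", {
  withr::with_seed(7, {
    for (i in 1:15) {
      ksv <- 10^runif(1, 3, 6)
      tau0 <- 10^runif(1, -9.5, -8.5)
      fit <- stern_volmer_fit(make_static_series(ksv, n = 1), tau0_s = tau0)
      expect_equal(fit$kq_M_inv_s_inv / fit$ksv_M_inv, 1 / tau0, tolerance = 1e-12)
    }
  })
})

test_that("double-log binding fit returns Kb and n to machine precision", {
  s <- make_static_series(3.14e5, n = 1.1)
  fit <- modified_sv_fit(s)
  expect_equal(fit$kb_M_inv, 3.14e5, tolerance = 1e-10)
  expect_equal(fit$n_sites, 1.1, tolerance = 1e-10)
  expect_equal(fit$kb_M_inv, 10^fit$log10_kb, tolerance = 1e-12)
  expect_length(fit$excluded_points, 0)

  ## independent closed-form OLS oracle on the transformed data
  q <- s$points$quencher_conc_M[-1]
  y <- log10(s$f0 / s$points$fluorescence[-1] - 1)
  o <- ols_oracle(log10(q), y)
  expect_equal(fit$log10_kb, unname(o["intercept"]), tolerance = 1e-9)
  expect_equal(fit$n_sites, unname(o["slope"]), tolerance = 1e-9)
})

test_that("single-site model structure: doubling [Q] shifts the log-ratio by log10(2)", {
  kb <- 1e3
  q <- c(1e-5, 2e-5)
  ratio <- kb * q  # F0/F - 1 with n = 1
  expect_equal(diff(log10(ratio)), log10(2), tolerance = 1e-12)
  fit <- modified_sv_fit(make_static_series(kb, n = 1))
  expect_equal(fit$n_sites, 1, tolerance = 1e-9)
})

test_that("unquenched points are excluded from the double-log fit and recorded", {
  q <- seq(0, 50e-6, by = 5e-6)
  f <- 1000 / (1 + 2e4 * q)
  f[2] <- 1000  # first titration point shows no quenching: F = F0
  s <- titration_series(q, f)
  fit <- modified_sv_fit(s)
  expect_equal(fit$excluded_points, 2L)
  expect_equal(fit$n_points_used, 9)

  f_all <- rep(1000, length(q))
  expect_error(modified_sv_fit(titration_series(q, f_all)),
               class = "specbind_insufficient_data_error")
})

test_that("Stern-Volmer and binding constants coincide for a single site", {
  s <- make_static_series(2.5e4, n = 1)
  expect_equal(stern_volmer_fit(s)$ksv_M_inv, modified_sv_fit(s)$kb_M_inv,
               tolerance = 1e-6)
})

test_that("mechanism classifier separates static, dynamic and ambiguous evidence", {
  fit_at <- function(ksv, t_k, tau0 = 1e-9) {
    stern_volmer_fit(make_static_series(ksv, n = 1, temperature_K = t_k), tau0_s = tau0)
  }
  ## temperature-decreasing Ksv with kq >> 2e10: static (the albumin pattern)
  static <- classify_mechanism(list(fit_at(5.03e4, 298), fit_at(3.20e4, 303),
                                    fit_at(2.30e4, 310)))
  expect_identical(static$call, "static")
  expect_identical(static$ksv_temperature_trend, "decreasing")
  expect_true(static$kq_exceeds_diffusion_limit)

  ## increasing Ksv with kq below the diffusion limit: dynamic
  dynamic <- classify_mechanism(list(fit_at(1e2, 298, tau0 = 1e-7),
                                     fit_at(2e2, 303, tau0 = 1e-7),
                                     fit_at(3e2, 310, tau0 = 1e-7)))
  expect_identical(dynamic$call, "dynamic")

  ## mixed evidence: decreasing trend but kq below the limit
  ambiguous <- classify_mechanism(list(fit_at(3e2, 298, tau0 = 1e-7),
                                       fit_at(2e2, 303, tau0 = 1e-7)))
  expect_identical(ambiguous$call, "ambiguous")

  expect_error(classify_mechanism(list(fit_at(1e4, 298), fit_at(2e4, 298))),
               class = "specbind_domain_error")
  expect_error(classify_mechanism(list(fit_at(1e4, 298))),
               class = "specbind_insufficient_data_error")
})

test_that("displacement analysis reproduces the albumin site-II call", {
  for (tbl in list(hsa_marker_ksv, bsa_marker_ksv)) {
    rep <- displacement_analysis(tbl$free,
                                 list(PBZ = tbl$PBZ, WAR = tbl$WAR, DIA = tbl$DIA),
                                 albumin_site_map)
    expect_identical(rep$primary_site_call, "site II")
    expect_identical(rep$primary_marker, "DIA")
  }
  ## fractional decreases from the printed HSA constants
  rep <- displacement_analysis(hsa_marker_ksv$free,
                               list(PBZ = hsa_marker_ksv$PBZ, WAR = hsa_marker_ksv$WAR,
                                    DIA = hsa_marker_ksv$DIA),
                               albumin_site_map)
  frac <- setNames(rep$markers$fractional_decrease, rep$markers$marker)
  expect_equal(unname(frac["DIA"]), 1 - 6.3e3 / 5.03e4, tolerance = 1e-12)
  expect_equal(unname(frac["PBZ"]), 1 - 1.20e4 / 5.03e4, tolerance = 1e-12)
  expect_equal(unname(frac["WAR"]), 1 - 1.7e4 / 5.03e4, tolerance = 1e-12)
  expect_equal(unname(round(frac[c("DIA", "PBZ", "WAR")], 3)),
               c(0.875, 0.761, 0.662))
  ## site I competition is strong enough to flag as a secondary site
  expect_identical(rep$secondary_sites, "site I")

  none <- displacement_analysis(5e4, list(DIA = 5e4, WAR = 5e4), albumin_site_map)
  expect_identical(none$primary_site_call, "none")
  expect_true(all(none$markers$fractional_decrease == 0))

  expect_error(displacement_analysis(5e4, list(XYZ = 1e4), albumin_site_map),
               class = "specbind_config_error")
})

test_that("titration tables round-trip through delimited text", {
  s <- make_static_series(1e5, n = 1.1, protein_label = "HSA")
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration(s, path)
  back <- read_titration(path, protein_label = "HSA", temperature_K = 298)
  expect_equal(back$points$quencher_conc_M, s$points$quencher_conc_M, tolerance = 1e-12)
  expect_equal(back$points$fluorescence, s$points$fluorescence, tolerance = 1e-12)
  expect_equal(back$f0, s$f0)
})
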