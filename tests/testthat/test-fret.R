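test_that("overlap integral matches the fine-grid quadrature oracle", {
  pair <- generate_overlap_pair(donor_center_nm = 340, donor_sigma_nm = 15,
                                acceptor_center_nm = 330, acceptor_sigma_nm = 12,
                                epsilon_peak = 4000, grid_step_nm = 1)
  j <- overlap_integral(pair$donor, pair$acceptor, range_nm = pair$range_nm)
  expect_equal(j$j_nm4_M_inv_cm_inv, pair$analytic_j_nm4_M_inv_cm_inv,
               tolerance = 5e-4)
  expect_equal(j$j_cm3_M_inv, j$j_nm4_M_inv_cm_inv * 1e-28, tolerance = 1e-12)
})

test_that("overlap integral edge cases: zero acceptor, zero donor, narrow donor", {
  donor <- gaussian_spectrum(340, from = 300, to = 400)
  zero_eps <- spectrum(seq(300, 400), rep(0, 101), kind = "molar_absorptivity")
  expect_equal(overlap_integral(donor, zero_eps)$j_nm4_M_inv_cm_inv, 0)

  zero_donor <- spectrum(seq(300, 400), rep(0, 101), kind = "emission")
  eps_flat <- spectrum(seq(300, 400), rep(2000, 101), kind = "molar_absorptivity")
  expect_error(overlap_integral(zero_donor, eps_flat), class = "specbind_domain_error")

  ## donor mass concentrated near lambda0 with flat epsilon: J -> eps0 lambda0^4
  narrow <- gaussian_spectrum(350, sigma = 0.2, from = 300, to = 400, step = 0.02)
  eps_fine <- spectrum(seq(300, 400, by = 0.02), rep(2000, 5001),
                       kind = "molar_absorptivity")
  expect_equal(overlap_integral(narrow, eps_fine)$j_nm4_M_inv_cm_inv,
               2000 * 350^4, tolerance = 1e-5)

  ## units must be molar absorptivity, not raw absorbance
  abs_sp <- spectrum(seq(300, 400), rep(0.01, 101), kind = "absorbance")
  expect_error(overlap_integral(donor, abs_sp), class = "specbind_domain_error")
  ## disjoint grids inside the window
  far <- gaussian_spectrum(800, from = 700, to = 900)
  expect_error(overlap_integral(donor, spectrum(far$wavelengths_nm, far$signal,
                                                kind = "molar_absorptivity")),
               class = "specbind_window_error")
})

test_that("overlap integral is invariant to donor intensity rescaling", {
  pair <- generate_overlap_pair()
  j1 <- overlap_integral(pair$donor, pair$acceptor, pair$range_nm)$j_nm4_M_inv_cm_inv
  scaled <- pair$donor; scaled$signal <- scaled$signal * 137.5
  j2 <- overlap_integral(scaled, pair$acceptor, pair$range_nm)$j_nm4_M_inv_cm_inv
  expect_equal(j1, j2, tolerance = 1e-12)
  expect_equal(forster_radius(j1), forster_radius(j2), tolerance = 1e-12)
})

test_that("trapezoid J converges at second order where the band is truncated", {
  j_at <- function(h) {
    p <- generate_overlap_pair(grid_step_nm = h)
    overlap_integral(p$donor, p$acceptor, range_nm = c(310, 370))$j_nm4_M_inv_cm_inv
  }
  j_fine <- j_at(0.01)
  e1 <- abs(j_at(1) - j_fine); e2 <- abs(j_at(0.5) - j_fine)
  expect_equal(e1 / e2, 4, tolerance = 0.15)  # halving h quarters the error
})

test_that("Forster radius follows the sixth-root scaling and unit dialect", {
  cfg <- fret_config()  # kappa^2 = 2/3, n = 1.336, phi = 0.15
  expect_equal(forster_radius(0, cfg), 0)
  j0 <- 5e12
  expect_equal(forster_radius(64 * j0, cfg), 2 * forster_radius(j0, cfg),
               tolerance = 1e-12)
  ## direct evaluation with the 1e-28 nm^4 -> cm^3 conversion
  expect_equal(forster_radius(2.11e13, cfg), 1.9687, tolerance = 1e-4)
  expect_error(forster_radius(-1, cfg), class = "specbind_domain_error")
  expect_error(fret_config(kappa_squared = 5), class = "specbind_domain_error")
  expect_error(fret_config(quantum_yield = 0), class = "specbind_domain_error")
})

test_that("transfer efficiency from intensities and distances is consistent", {
  expect_equal(efficiency_from_intensity(1000, 1000), 0)
  expect_equal(efficiency_from_intensity(290, 1000), 0.71)
  expect_equal(efficiency_from_intensity(380, 1000), 0.62)
  expect_error(efficiency_from_intensity(1100, 1000), class = "specbind_domain_error")

  expect_equal(efficiency_from_distance(1.89, 1.89), 0.5)
  expect_gt(efficiency_from_distance(1e-6, 1.89), 1 - 1e-6)  # r -> 0 gives E -> 1
  ## brute-force sixth-power evaluation at the reported distance
  expect_equal(efficiency_from_distance(1.43, 1.89),
               (1.89 / 1.43)^6 / (1 + (1.89 / 1.43)^6), tolerance = 1e-12)
  expect_equal(round(efficiency_from_distance(1.43, 1.89), 3), 0.842)

  ## strictly decreasing in r, mapping onto (0, 1)
  r <- seq(0.1, 10, by = 0.1)
  e <- efficiency_from_distance(r, 1.89)
  expect_true(all(diff(e) < 0) && all(e > 0) && all(e < 1))
})

test_that("efficiency <-> distance round-trips to 1e-12 relative", {
  expect_equal(distance_from_efficiency(0.5, 1.89), 1.89, tolerance = 1e-12)
  for (r in c(0.5, 1.0, 2.0)) {
    expect_equal(distance_from_efficiency(efficiency_from_distance(r, 1.89), 1.89),
                 r, tolerance = 1e-12)
  }
  expect_equal(distance_from_efficiency(0.71, 1.89),
               1.89 * (0.29 / 0.71)^(1 / 6), tolerance = 1e-12)
  expect_error(distance_from_efficiency(1, 1.89), class = "specbind_domain_error")
  expect_error(distance_from_efficiency(0, 1.89), class = "specbind_domain_error")
})

test_that("the Forster validity window is strict", {
  expect_true(forster_window_check(1.43, 1.89))
  expect_false(forster_window_check(0.5 * 1.89, 1.89))
  expect_false(forster_window_check(1.5 * 1.89, 1.89))
  expect_false(forster_window_check(3 * 1.89, 1.89))
  expect_error(forster_window_check(-1, 1.89), class = "specbind_domain_error")
})

test_that("fret_analysis composes the full chain coherently", {
  pair <- generate_overlap_pair()
  res <- fret_analysis(pair$donor, pair$acceptor, f = 290, f0 = 1000,
                       range_nm = pair$range_nm)
  expect_equal(res$efficiency, 0.71)
  expect_equal(res$r_nm, distance_from_efficiency(0.71, res$r0_nm), tolerance = 1e-12)
  expect_equal(res$j_cm3_M_inv, res$j_nm4_M_inv_cm_inv * 1e-28)
  expect_identical(res$forster_window_ok, forster_window_check(res$r_nm, res$r0_nm))
})
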