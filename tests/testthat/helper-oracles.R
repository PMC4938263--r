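# Shared fixtures and independent oracles for the fit routines.

## Closed-form ordinary-least-squares oracle via the normal equations,
## independent of stats::lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

## Noiseless static-quenching titration following F = F0 / (1 + Kb [Q]^n).
make_static_series <- function(kb, n = 1, f0 = 1000,
                               q = seq(5e-6, 50e-6, by = 5e-6),
                               temperature_K = 298, include_zero = TRUE, ...) {
  f <- f0 / (1 + kb * q^n)
  if (include_zero) {
    titration_series(c(0, q), c(f0, f), temperature_K = temperature_K, ...)
  } else {
    titration_series(q, f, f0 = f0, temperature_K = temperature_K, ...)
  }
}

## Gaussian emission band sampled on a 1 nm grid.
gaussian_spectrum <- function(center, sigma = 15, peak = 1000, kind = "emission",
                              from = center - 5 * sigma, to = center + 5 * sigma,
                              step = 1) {
  wl <- seq(from, to, by = step)
  spectrum(wl, peak * exp(-(wl - center)^2 / (2 * sigma^2)), kind = kind)
}

## Table-style printed inputs reused across tests (binding-study reference
## values for the two albumins).
hsa_kb_by_temp <- data.frame(temperature_K = c(298, 303, 310),
                             kb_M_inv = c(3.14e5, 2.22e5, 1.12e5))
bsa_kb_by_temp <- data.frame(temperature_K = c(298, 303, 310),
                             kb_M_inv = c(1.00e5, 5.57e4, 3.22e4))
hsa_marker_ksv <- list(free = 5.03e4, PBZ = 1.20e4, WAR = 1.7e4, DIA = 6.3e3)
bsa_marker_ksv <- list(free = 3.50e4, PBZ = 1.02e4, WAR = 1.8e4, DIA = 6.4e3)
albumin_site_map <- c(PBZ = "site I", WAR = "site I", DIA = "site II")
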