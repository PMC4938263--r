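---
title: "Spectroscopic binding analysis with specbind: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic binding analysis with specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

# Scope

`specbind` implements the steady-state optical workflow used to characterise
reversible small-molecule binding to fluorescent proteins, with serum albumin
titrated by a quenching ligand as the motivating system: quenching fits and
mechanism calls, binding thermodynamics, site-marker displacement, FRET
distance estimation, and Stokes–Einstein sizing, plus a synthetic-data
generator that makes every stage verifiable against known ground truth.

# Models and assumptions

## Quenching fits

The Stern–Volmer fit regresses $F_0/F$ on $[Q]$ by ordinary least squares
with a **free intercept**. The model predicts an intercept of exactly 1;
forcing it there would silently absorb blank-subtraction or normalisation
errors into the slope, so instead the intercept is reported and flagged (with
a warning) when it departs from 1 by more than 0.1. For data generated by a
superlinear binding law ($n > 1$) the linear fit legitimately lands below 1 —
the flag is a diagnostic, not an error.

The binding fit uses the double-logarithmic transform
$\log_{10}(F_0/F - 1) = \log_{10} K_b + n \log_{10}[Q]$. Base-10 logarithms
are used throughout this transform (natural logs would change the
intercept-to-$K_b$ mapping); the thermodynamic relations below use natural
logs. Points with $F_0/F - 1 \le 0$ have no defined transform; they are
dropped deterministically and their indices recorded in the fit object, so
every exclusion is auditable. $[Q]$ is the total added quencher
concentration: no free-ligand correction is applied, matching how such
titrations are conventionally analysed. The untransformed hyperbola is
deliberately not fitted nonlinearly — the package reproduces the
linear-transform estimates that the field reports, and the two coincide
exactly on noiseless single-site data (a tested invariant).

## Mechanism classification

Static (ground-state complex) quenching is called only on joint evidence:
$K_{sv}$ strictly decreasing with temperature **and** every apparent
$k_q = K_{sv}/\tau_0$ above the diffusion-controlled ceiling of
$2.0 \times 10^{10}\,\mathrm{M^{-1}s^{-1}}$; the strict converse yields
"dynamic", anything else "ambiguous". The trend test is strict monotonicity
over the supplied temperatures rather than a regression significance test:
with the customary three temperatures a slope test has no power, and
monotonicity is what practitioners actually read off the table. $\tau_0$
defaults to $10^{-9}$ s, the integral tryptophan lifetime.

## Thermodynamics

$\Delta G = -RT\ln K_b$ per temperature and an **unweighted** van't Hoff OLS
of $\ln K_b$ on $1/T$ give $\Delta H$ (kcal/mol) and $\Delta S$
(cal mol$^{-1}$ K$^{-1}$), under the constant-$\Delta H$ assumption that is
all a three-point, 12 K temperature window can support; no heat-capacity
extension is attempted, and with three points any weighting scheme would be
unidentifiable. $R$ defaults to 1.987 cal mol$^{-1}$ K$^{-1}$ (configurable;
the choice affects the fourth digit). Published tables frequently label the
entropic column "$\Delta S$" while printing numbers that are actually
$T\Delta S$ in kcal/mol; the package therefore always reports **both**
$\Delta S$ (from the intercept) and $T\Delta S = \Delta H - \Delta G$ per
temperature, with units attached, so the ambiguity cannot propagate. Force
classification follows the usual sign rules, with the ionic rule
($\Delta H \approx 0$, $\Delta S > 0$) tested first under a configurable
$|\Delta H| \le 1$ kcal/mol threshold so a small positive $\Delta H$ is not
misread as hydrophobic.

## Displacement analysis

Competition is quantified as the fractional decrease
$1 - K_{sv}^{+marker}/K_{sv}^{free}$; the primary site call is the Sudlow
site of the marker with the largest decrease, and any other marker whose
decrease exceeds 0.5 flags its site as secondary. The 0.5 threshold encodes
the common reading that a halved quenching constant still marks a site that
"cannot be neglected" while a ten-fold drop dominates.

## FRET

The overlap integral is assembled with $\lambda$ in nm and $\varepsilon$ in
M$^{-1}$cm$^{-1}$, giving $J$ in nm$^4$M$^{-1}$cm$^{-1}$, and converted by
$10^{-28}$ to cm$^3$M$^{-1}$ before entering
$R_0^6 = 8.79\times10^{-25}\,\kappa^2 n^{-4}\phi J$ (cm$^6$). This unit
dialect is stated explicitly because it is the single most common source of
order-of-magnitude errors in published FRET tables; both expressions of $J$
are always emitted together. Published parameter sets assembled under
unstated conventions are not always mutually consistent under these
equations — the package computes each quantity independently and flags the
$0.5R_0 < r < 1.5R_0$ validity window (strict inequalities) rather than
reconciling inconsistent inputs. Defaults $\kappa^2 = 2/3$ (freely rotating
dipoles), $n = 1.336$ (dilute aqueous buffer), $\phi = 0.15$ (albumin
tryptophan); integration range defaults to 300–400 nm, the tryptophan-donor
window. Quadrature is composite trapezoid on the union grid with linear
interpolation and never extrapolation: spectra are smooth and densely
sampled, and trapezoid is auditable; spline quadrature buys nothing here
(the tested agreement with a 0.01 nm oracle is well under 0.05% at a 1 nm
grid). Efficiency comes from the equimolar donor–acceptor intensity pair,
$E = 1 - F/F_0$; lifetime-based efficiencies and $\kappa^2$ estimation are
out of scope.

## Hydrodynamics

$R_h = k_B T/(6\pi\eta D)$ in SI internally, nm at the reporting boundary.
When no viscosity is supplied, water viscosity comes from the standard
Vogel-type correlation $\eta = 2.414\times10^{-5}\cdot10^{247.8/(T-140)}$
Pa s, chosen over a lookup table because it is smooth, covers 273–373 K, and
agrees with handbook values to well under 1% in the biochemical range
(8.937$\times 10^{-4}$ Pa s at 298 K). Size-change reports only call a
direction (compaction vs expansion/aggregation) beyond a 5% fractional
change — below typical instrument polydispersity, changes are noise. No
shape correction to the Stokes sphere is applied, and autocorrelation
analysis is upstream of this package: it starts from $D$ or $R_h$.

# The synthetic-data generator

Static quenching is generated through the bound-fraction model — a
non-fluorescent ground-state complex, $F = F_0/(1 + K_b[Q]^n)$ — so the
double-log transform is exact by construction and every estimator can be
validated as a generator/estimator inverse pair. Temperature series draw
$K_b(T)$ from the van't Hoff law; the default ground truth
($K_b = 3.14\times10^5$ M$^{-1}$, $n = 1.1$,
$\Delta H = -15.806$ kcal/mol, $\Delta S = -27.89051$ cal mol$^{-1}$K$^{-1}$
— the value pinning $K_b(298\,\mathrm{K})$ to the stated constant, computed
once from $\Delta S = R\ln K_b + \Delta H/T$) describes a tight exothermic
single-site binder titrated 0–50 µM in 5 µM steps against 5 µM protein at
298/303/310 K, the standard albumin titration design. Noise is multiplicative
Gaussian on $F$ (CV-parameterised, quenched points only, so the $[Q]=0$
anchor stays exact), reflecting photometric noise; every generator is a pure
function of (parameters, seed). Emission bands are Gaussian in wavelength
(not wavenumber) with the band center interpolating from the free to the
bound position with the bound fraction — adequate for exercising peak/shift
logic, which is all they are for.

What the generator does **not** emulate: inner-filter effects (the analysis
applies no inner-filter correction either, so the pair is consistent),
photobleaching, instrument response, scattering baselines, or correlated
noise. Passing the recovery suites therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to every instrument
artefact in real spectra.

A note on what parameter recovery can promise: with the standard 10-point,
one-decade concentration grid, the double-log intercept sits nearly five
decades in $\log_{10}[Q]$ from the data centroid. Slope noise is therefore
amplified into the intercept, and at 1% photometric noise the median
relative error of $K_b$ (tens of percent) is intrinsically an order of
magnitude worse than that of $n$ (about 1–2%) — a property of the
experimental design, not of the fitting code, which recovers both exactly at
zero noise. Widening the concentration range, not replicating the titration,
is the effective remedy.

# Numerical choices

* **Peak location.** Argmax on the grid, then three-point parabolic
  interpolation through the maximum and its neighbours when the maximum is
  interior (fall back to the grid point when the parabola degenerates, i.e.
  its leading coefficient is non-negative, and clamp the refined vertex to
  the bracketing interval). On 1 nm grids this is what resolves 3 nm
  synchronous-scan shifts that raw argmax would quantise. Whether published
  band maxima were read raw or interpolated is usually unstated; refinement
  is this package's choice and can be disabled (`refine = FALSE`).
* **Grid identity tolerance** for blank subtraction: $10^{-6}$ nm.
  Resampling across differing grids (FRET only) is linear interpolation onto
  the intersection range, never extrapolation.
* **Sign convention:** negative peak shift = blue shift, stated in every
  report object.
* **Degenerate inputs** are classed errors, not NA propagation: fewer than 3
  usable titration points, non-positive intensities, duplicate wavelengths
  or temperatures, empty window overlap, markers missing from the site map,
  a missing ligand-free baseline. A flat titration returns $K_{sv} = 0$ with
  an undefined (NA) $R^2$ rather than failing.
* **Report discipline:** every numeric in the study report is a
  `{value, unit}` pair and `validate_study_report()` rejects unit-less
  numerics; reports are deterministic given config + inputs except the
  timestamp.

# Problem sizes used in the test suite

Titration fixtures use the 11-point (0–50 µM) design throughout; the
stochastic recovery suite runs 100 seeded replicates at 1% noise; quadrature
checks compare 1 nm and 0.5 nm grids against a 0.01 nm oracle on a truncated
window where trapezoid error is genuinely $O(h^2)$. These sizes mirror the
experimental design the package targets and keep the whole suite in the
seconds range.

# Known limitations

No global multi-site binding models, no nonlinear fit of the untransformed
quenching hyperbola, no lifetime measurements, no $\Delta C_p$ or nonlinear
van't Hoff, no inner-filter simulation, no vendor binary formats, no
excitation–emission matrices. The displacement call is a ranking of
fractional decreases, not a structural assignment: it identifies which
marker competes hardest, and inherits that marker's site assignment.
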