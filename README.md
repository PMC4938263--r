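# specbind

Analysis of small-molecule binding to proteins from steady-state optical
spectroscopy, built around the classic serum-albumin drug-binding workflow:
fluorescence quenching titrations, binding thermodynamics, site-marker
displacement, Förster resonance energy transfer (FRET) and hydrodynamic
sizing. The package is aimed at wet-lab groups who titrate a fluorescent
protein (typically an albumin, followed through its tryptophan emission) with
a ligand and want every downstream number — binding constant, binding site,
driving forces, donor–acceptor distance, size change — computed reproducibly
from the raw titration tables and spectra.

## The models

**Quenching.** For a quencher at concentration [Q], the Stern–Volmer relation

    F0/F = 1 + Ksv [Q] = 1 + kq τ0 [Q]

gives the quenching constant Ksv (M⁻¹) as the slope of F0/F vs [Q], and the
bimolecular rate constant kq = Ksv/τ0 (τ0 ≈ 10⁻⁹ s for tryptophan). Static
(complex-forming) quenching is recognised by Ksv falling with temperature and
kq far above the diffusion-controlled ceiling of 2×10¹⁰ M⁻¹s⁻¹. The
double-logarithmic (modified Stern–Volmer) plot

    log10(F0/F − 1) = log10 Kb + n log10 [Q]

yields the binding constant Kb and the apparent number of binding sites n.

**Thermodynamics.** ΔG = −RT ln Kb per temperature, and the van't Hoff fit of
ln Kb against 1/T gives ΔH (slope × −R) and ΔS (intercept × R), with
R = 1.987 cal mol⁻¹ K⁻¹. Sign rules on (ΔH, ΔS) classify the dominant
interaction forces (both negative → hydrogen bonding / van der Waals).

**FRET.** The overlap integral J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ (λ in nm, ε in
M⁻¹cm⁻¹) enters R0⁶ = 8.79×10⁻²⁵ κ² n⁻⁴ φ J (J converted to cm³M⁻¹), and
E = 1 − F/F0 = R0⁶/(R0⁶ + r⁶) gives the donor–acceptor distance r, flagged
against the 0.5 R0 < r < 1.5 R0 validity window.

**Hydrodynamics.** Stokes–Einstein: Rh = kB T / (6π η D).

A synthetic-data module generates titrations, temperature series, spectra and
displacement sets from known ground truth so that the whole pipeline is
testable end to end, and `run_study()` drives every stage from one YAML
configuration into a unit-labelled JSON report.

## Worked example

```r
library(specbind)

## published HSA binding constants at three temperatures
th <- vant_hoff_fit(c(298, 303, 310), c(3.14e5, 2.22e5, 1.12e5))
th
#> van't Hoff analysis
#>   dH = -15.908 kcal/mol   dS = -28.161 cal/(mol K)   R^2 = 0.9897
#>   298 K: Kb = 3.14e+05 M^-1, dG = -7.495 kcal/mol, TdS = -8.413 kcal/mol
#>   303 K: Kb = 2.22e+05 M^-1, dG = -7.412 kcal/mol, TdS = -8.496 kcal/mol
#>   310 K: Kb = 1.12e+05 M^-1, dG = -7.161 kcal/mol, TdS = -8.746 kcal/mol
#>   dominant forces: hydrogen bonding / van der Waals
```

Binding is spontaneous (ΔG ≈ −7.5 kcal/mol), strongly exothermic
(ΔH ≈ −15.9 kcal/mol) and entropically penalised, the signature of hydrogen
bonding and van der Waals contacts. A full synthetic study:

```r
cfg <- simulate_study(tempfile("study"), ground_truth(noise_cv = 0.01), seed = 1)
report <- run_study(cfg)
render_tables(report, print = TRUE)
#> # Binding and thermodynamic parameters
#> protein  temperature_K  n      Ksv_M_inv  kq_M_inv_s_inv  Kb_M_inv  dH_kcal_mol  dG_kcal_mol  TdS_kcal_mol
#> SYN      298            1.102  119000     1.19e+14        318800    -17.988      -7.504       -10.48
#> SYN      303            1.095  77050      7.705e+13       191900    -17.988      -7.324       -10.66
#> SYN      310            1.089  41970      4.197e+13       98290     -17.988      -7.081       -10.91
#>
#> # Site-marker displacement
#> protein  marker  site     Ksv_with_marker_M_inv  fractional_decrease  primary_site_call
#> SYN      DIA     site II  14810                  0.8755               site II
#> SYN      PBZ     site I   28690                  0.7589               site II
#> SYN      WAR     site I   40100                  0.6631               site II
#> ...
```

The fitted Kb (318800 vs a generating 314001 M⁻¹ at 298 K), n (1.102 vs 1.1)
and the site-II displacement call round-trip the ground truth recorded in the
study's `manifest.yaml` to within the 1% photometric noise requested; the
van't Hoff ΔH is the quantity most sensitive to that noise (−17.99 vs a
generating −15.81 kcal/mol here), since it leverages small Kb errors across
only three temperatures.

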