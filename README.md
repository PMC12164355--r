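# plasmiso

Quantitative analysis of **nanoplasmonic isosbestic points** — the
wavelength at which the extinction spectra of a gold-nanoparticle
dispersion, recorded at different concentrations of a soft template
(liposomes, extracellular vesicles), all intersect.

## The science

When ~12 nm gold nanoparticles (AuNPs) cluster on a vesicle surface,
the system contains two plasmonic populations: free particles (single
resonance near 524 nm) and clusters, whose coupled resonance red-shifts
as the surface-to-surface interparticle spacing ⟨sp⟩ shrinks. Every
observed spectrum is a convex mixture

    E_f(λ) = f · E_coupled(λ) + (1 − f) · E_uncoupled(λ),

so all spectra pass through the crossing of the two endpoints — the
isosbestic wavelength λ_iso. λ_iso follows a decreasing sigmoid in
⟨sp⟩,

    λ_iso(⟨sp⟩) = (λ_A − λ_B) / (1 + exp((⟨sp⟩ − sp0)/k)) + λ_B,

which can be inverted in closed form to estimate ⟨sp⟩ — and, because
membrane stiffness sets the cluster spacing, to read out vesicle
mechanics from a plain UV–vis measurement, independent of vesicle
concentration. Cluster energetics come from small-angle X-ray
scattering: a Schulz-polydisperse sphere form factor times Baxter's
sticky-hard-sphere structure factor (Percus–Yevick) yields the cluster
volume fraction φ and stickiness τ, and the effective pair potential
u0/kBT = ln(12 τ ε).

The package provides:

* gold optical constants (embedded table + analytic fallback), full Mie
  cross sections, and peak utilities;
* a coupled-dipole solver for cluster spectra (63-particle radial
  protocol, 1D chains, field-enhancement maps);
* isosbestic detection in spectral families, the ⟨sp⟩ sweep, sigmoid
  calibration/inversion with error propagation, and a membrane-stiffness
  calibration;
* sticky-hard-sphere SAXS fitting, structure-factor extraction and the
  τ → u0 conversion;
* synthetic-data generators (mixture series, SAXS curves, calibration
  sets) with recorded ground truth;
* plain-text I/O for spectra, SAXS profiles, geometries and
  calibrations, plus a small CLI (`inst/cli/plasmiso`).

## Worked example

```r
library(plasmiso)

## 1. a synthetic concentration series (AuNPs 4.4e12/mL, vesicles
##    6e10-3.2e11/mL, 14 particles per vesicle at saturation)
ser <- generateMixtureSeries(spectralScenario(seed = 42))
res <- isosbesticFromFamily(ser)
sprintf("lambda_iso = %.2f nm, dispersion = %.2f nm, present = %s",
        res$lambda_iso, res$dispersion, res$is_isosbestic)
#> "lambda_iso = 536.31 nm, dispersion = 0.76 nm, present = TRUE"

## 2. calibrate lambda_iso against spacing and invert an EV-style reading
sw  <- isosbesticSweep(seq(0.2, 1.6, by = 0.2))
cal <- fitSigmoid(sw$sp, sw$lambda_iso)
cal
#> SigmoidCalibration (abscissa: sp)
#>   lambda_A    537.9889 +- 0.0248
#>   lambda_B    525.9375 +- 0.0108
#>   x0            0.7012 +- 0.0012
#>   k             0.2501 +- 0.0011
inv <- invertSigmoid(531, cal, sigma_lambda = 1)
sprintf("sp = %.2f +/- %.2f nm", inv$sp, inv$sd)
#> "sp = 0.78 +/- 0.09 nm"

## 3. sticky-hard-sphere analysis of a soft-template SAXS curve
prof <- generateSAXSProfile(saxsScenario(), preset = "DOPC")
fitStickyHardSphere(prof, mean_radius = 6.9, polydispersity = 0.13)
#> Sticky-hard-sphere fit
#>   volume fraction phi = 0.0189 +- 3e-16
#>   stickiness tau      = 0.0634 +- 5.1e-16
#>   u0 (eps = 0.02)     = -4.185 kBT
#>   chi2/dof = 2.236e-32
```

The isosbestic wavelength (536.3 nm) sits at the crossing of the
free-particle and cluster endpoints; its sub-1.5 nm dispersion across
consecutive spectrum pairs is what qualifies it as isosbestic. The
inversion turns a measured λ_iso = 531 ± 1 nm into a sub-nanometer
cluster spacing. The SAXS fit recovers the generating volume fraction
and stickiness exactly on a noise-free curve, and the reconstructed
pair potential (−4.19 kBT) indicates a strongly attractive well on the
softest membranes.

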