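---
title: "Nanoplasmonic isosbestic points: models, calibrations and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoplasmonic isosbestic points: models, calibrations and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmiso)
```

## The physical picture

Citrate-stabilized gold nanoparticles (AuNPs, ~12 nm diameter) adsorb
spontaneously onto lipid vesicles and cluster there. A dispersion
containing both free particles and vesicle-bound clusters is a
*two-population* optical system: its extinction spectrum is a convex
mixture

$$ E_f(\lambda) = f\,E_{\mathrm{coupled}}(\lambda) +
   (1-f)\,E_{\mathrm{uncoupled}}(\lambda), $$

where $f$ is the fraction of particles in clusters. Whatever $f$ is, all
mixture spectra pass through any wavelength where the two endpoint
spectra cross — an *isosbestic point* $\lambda_{iso}$. Because the
coupled endpoint red-shifts as the surface-to-surface interparticle
spacing $\langle sp\rangle$ inside clusters shrinks, $\lambda_{iso}$
moves with $\langle sp\rangle$; and because membrane stiffness controls
how tightly particles pack on a vesicle, $\lambda_{iso}$ ultimately
reports the mechanics of the template membrane, independently of the
vesicle concentration. The package implements every stage of that chain
and a synthetic-data generator that exercises it with known ground
truth.

## Gold optical constants

The embedded dielectric table is a Johnson–Christy-style compilation of
gold $n,k$ values on the 1.39–4.12 eV grid, converted to complex
relative permittivity and interpolated linearly in wavelength
(`goldDielectric("table")`, the default). An analytic fallback
(`"drude_lorentz"`) — a Drude term plus two critical-point oscillators,
the standard analytic description of gold's interband edge — was fitted
once to the table; its frozen parameters reproduce the table within a
documented 5% maximum relative deviation over 400–800 nm. (A plain
Drude plus two symmetric Lorentzians cannot do better than about 5.5%
here; the critical-point phase factors are what capture the asymmetric
interband onset.)

The surrounding medium defaults to a refractive index of 1.343. The
source protocol fixes "the real part of permittivity" of the lipid
environment at 1.343, which is ambiguous between $\varepsilon_m=1.343$
($n\approx1.159$) and $n=1.343$ ($\varepsilon_m\approx1.804$). Only the
latter reproduces the reported 524–525 nm single-particle resonance
(our Mie peak: 521.3 nm at $n=1.343$ versus 515 nm at
$\varepsilon_m=1.343$), so `Medium()` defaults to $n=1.343$; both
conventions remain selectable via the `permittivity` argument.

No mean-free-path (size-dependent) correction is applied to the bulk
permittivity by default; at 12 nm diameter the correction mainly
broadens the resonance slightly and would not move the peak or crossing
positions materially.

## Single-particle optics and peak location

`mieCrossSections()` evaluates the full multipole Mie series with the
size-adaptive Wiscombe truncation order. For the particle sizes of
interest ($x\approx0.1$) the series is dominated by the electric
dipole; the suite checks the $r^3$ (absorption) and $r^6$ (scattering)
scaling laws and agreement with the analytic finite-size dipole
polarizability (Clausius–Mossotti with dynamic-depolarization and
radiative-reaction corrections) within 5% up to $r=10$ nm.

`peakWavelengths()` reports local maxima with a relative prominence
filter (default 2% of the spectrum maximum) and refines each position
by a quadratic fit through the three surrounding samples, giving
sub-grid peak positions from 1–2 nm grids.

## The coupled-dipole cluster solver

Finite-element electromagnetics is replaced by the coupled-dipole
approximation: one induced point dipole per sphere with a radiatively
corrected polarizability, interacting through the full retarded dyadic
Green function. Extinction comes from the optical theorem, absorption
from per-dipole dissipation, scattering from their difference (checked
against far-field angular quadrature within 2% in the suite).

This choice keeps every mechanism of the study — distance-dependent
coupling, red shift, mixtures, isosbestic crossings — while remaining
dependency-free and fast (a 63-particle spectrum over 201 wavelengths
solves in under a second). Its known limitation is quantitative
fidelity at sub-nanometer gaps: the point-dipole field misses
multipolar contributions once the surface gap falls below roughly 0.15
particle radii, and the solver emits a fidelity warning there.
Consequences worth knowing:

* A 10-particle chain at $sp=0.3$ nm peaks at ~604 nm — comfortably red
  of the 580 nm landmark — but compact 3-particle subgroups reach only
  ~560 nm, short of the ~609 nm a full-wave solver reports for the same
  spacing. Sub-nm-gap positions from this solver are treated as
  qualitative anchors throughout.
* The solver's $\lambda_{iso}$ sweep is compressed (roughly 527→514 nm
  over $sp=0.3$–1.6 nm against the reported 537→527 nm) but strictly
  monotone, which is the property the calibrations rely on.

### Geometry conventions

The radial builder places 21 collinear three-particle subgroups
tangentially on one ring in the XY plane, with subgroup surface gaps
cycling through $\{0.75\,sp,\ sp,\ 1.25\,sp\}$ (seven subgroups each),
so the subgroup-averaged gap is exactly $sp$. The tangential
C$_{21}$ arrangement makes the in-plane response polarization-isotropic
to machine precision, matching the unpolarized-illumination argument of
the radial model. Ring radii are not prescribed by the source; our
convention separates subgroup surfaces by 300 nm. A convergence study
showed that at the minimal 4-radius separation the residual far-field
(retarded, $1/r$) coupling around the ring still shifts crossing
wavelengths by ~1 nm, while at 300 nm the shift is below 0.1 nm — the
margin is therefore a numerical-independence choice, not physics.

Chains (`buildChainGeometry()`) are uniform-gap and anisotropic;
unpolarized chain spectra are the Ex/Ey average. When comparing chain
and radial clusters *at equal* $\langle sp\rangle$, the comparison must
preserve the gap-variant composition: an ensemble of chains with gaps
$\{0.75\,sp, sp, 1.25\,sp\}$ matches the radial cluster within 0.1 nm
in $\lambda_{iso}$, whereas a single uniform-gap chain differs by up to
~1 nm purely through the composition, not the shape.

## Isosbestic detection

`findIsosbestic()` locates sign changes of the difference of two
spectra within a window (default 450–650 nm) and refines each crossing
by linear interpolation between bracketing grid points. With several
crossings, the one nearest the primary peak of the uncoupled spectrum —
the physically shared pivot of the two populations — is reported along
with the count.

For a family of spectra, `isosbesticFromFamily()` takes crossings of
consecutive pairs and declares an isosbestic point when all pairs cross
and the standard deviation of the crossing wavelengths is at most
1.5 nm — slightly looser than the ±1 nm with which experimental
$\lambda_{iso}$ values are reproducible. Consecutive-pair crossings are
the most noise-sensitive choice (position jitter scales as the noise
over the difference slope), which is deliberate: a family that passes
this test crosses consistently everywhere.

## The sigmoidal spacing law and its inversion

The calibration model is the four-parameter decreasing sigmoid

$$ \lambda_{iso}(\langle sp\rangle) =
   \frac{\lambda_{iso}^A - \lambda_{iso}^B}
        {1 + e^{(\langle sp\rangle - sp_0)/k}} + \lambda_{iso}^B, $$

with upper/lower limits $\lambda_{iso}^A > \lambda_{iso}^B$, inflection
$sp_0$ and slope factor $k>0$. `fitSigmoid()` uses
Levenberg–Marquardt least squares initialized from the data (limits
from the range, inflection at the steepest numerical gradient, $k$ from
the quartile spread) and returns the parameter covariance. The
published parameter values for this curve are not printed in the
available text, so calibrations are always refit, never hard-coded.

`invertSigmoid()` applies the closed-form inverse

$$ \langle sp\rangle = sp_0 + k\,
   \ln\!\left(\frac{\lambda_{iso}^A-\lambda_{iso}^B}
                   {\lambda_{iso}-\lambda_{iso}^B} - 1\right), $$

defined strictly on the open interval
$(\lambda_{iso}^B, \lambda_{iso}^A)$ — out-of-range inputs raise an
error rather than clamping — with uncertainty from first-order
propagation of the measurement error and the parameter covariance.
One documented discrepancy follows from strict monotonicity: reported
EV values pair $\lambda_{iso}=531$ nm with a *larger* spacing than
529 nm would give under any decreasing law (0.7 vs 0.6 nm). The
implementation keeps the strict inverse — a larger $\lambda_{iso}$
always maps to a smaller spacing — and the suite asserts the monotone
ordering, not the reported pairing. Similarly, the imaging-derived
spacing for the softest template (0.8 ± 0.2 nm) and the
isosbestic-derived ~0.3 nm are treated as two independent measurement
channels and never reconciled.

The membrane-stiffness calibration (`fitStiffnessMap()`) reuses the
same functional family with stiffness as abscissa after a Kendall-tau
monotonicity gate, and inverts identically.

## SAXS: sticky spheres

The scattered intensity is modelled as
$I(Q) = s\,P(Q)\,S(Q) + b$ in the decoupling approximation
(polydispersity enters $P$ only), matching common practice for this
model family. $P(Q)$ is the Schulz-averaged sphere form factor in exact
closed form: all required moments
$\mathbb{E}[R^m e^{2iQR}]$ of the gamma-distributed radius are
analytic, and a series branch below $QR\approx0.1$ avoids the
$Q^{-6}$ cancellation. The closed form agrees with adaptive quadrature
over the size distribution to $10^{-10}$.

$S(Q)$ is Baxter's sticky-hard-sphere factor in the Percus–Yevick
closure, from the smaller root of the quadratic for Baxter's
$\lambda$. Two conventions exist for the narrow attractive well: the
plain $(\phi,\tau)$ parameterization, and a perturbative rescaling
$\eta=\phi/(1-\epsilon)^3$ used by some fitting software. The package
defaults to the plain convention because the softest-template parameter
pair ($\phi=0.0189$, $\tau=0.0634$) sits *marginally inside the
forbidden region* under the rescaled convention
($\tau_{crit}=0.06342$) — the rescaling remains available via
`rescale = TRUE`. Limits are verified against independent routes:
$S\to1$ uniformly as $\phi\to0$, and $\tau\to\infty$ reproduces the
Ashcroft–Lekner Percus–Yevick hard-sphere factor to $10^{-3}$.

`fitStickyHardSphere()` fixes the form factor (from a free-particle
fit, mirroring the standard protocol) and fits scale, background,
$\phi$ and $\tau$ by weighted Levenberg–Marquardt ($1/\sigma_I^2$
weights when uncertainties are present, else $1/I$), reporting
covariance-based standard errors scaled by $\chi^2/\mathrm{dof}$ and
flagging bound-pinned parameters.

The effective pair potential uses the narrow-well identity
$\tau = e^{u_0/k_BT}/(12\,\epsilon)$, i.e.
$u_0/k_BT=\ln(12\,\tau\,\epsilon)$, with the well width
$\epsilon = sp/(\sigma_{hc}+sp)$ when a spacing is supplied
(`wellWidthFromSpacing()`). With $\epsilon=0.02$ (the value implied by
the softest template's ~0.3 nm spacing and a 13.8 nm core) this
reconstruction reproduces the softest-template potential within
0.005 $k_BT$ and preserves the full ordering across the stiffness
series; the exact per-sample $\epsilon$ values of the original analysis
are not published, so other rows may deviate by up to ~0.1 $k_BT$.

## What the synthetic generator emulates — and what it does not

`generateMixtureSeries()` produces a concentration series under the
saturation law $f=\min(1,\ c_{ves} N_{sat}/c_{AuNP})$ with
$N_{sat}=14$ particles per vesicle, AuNP concentration
$4.4\times10^{12}$/mL and vesicle concentrations spanning
$6\times10^{10}$–$3.2\times10^{11}$/mL — number ratios ~74/1 down to
~14/1, the regime where the isosbestic point emerges. Beyond a 10%
template excess over exact saturation, cluster-size heterogeneity is
emulated by per-spectrum random compression of the coupled endpoint's
red shift plus an amplitude factor, which removes the common crossing —
the documented loss of the isosbestic feature at high vesicle
concentration. Additive spectral noise defaults to $5\times10^{-4}$
absorbance units, the photometric noise of a modern benchtop
spectrophotometer near 1 AU; at this level consecutive-pair crossing
dispersion is 0.3–1.0 nm, consistent with the ±1 nm experimental
reproducibility.

The parametric (solver-independent) endpoints are two-Lorentzian
spectra: the coupling band's center decays exponentially with spacing
through the (0.3 nm, 609 nm) and (0.8 nm, 553 nm) anchors, and the
primary-band weight is chosen in closed form so the endpoints cross
exactly at the sigmoidal law's $\lambda_{iso}(\langle sp\rangle)$
(defaults $\lambda^A=538$, $\lambda^B=526$, $sp_0=0.7$ nm,
$k=0.25$ nm). The generated families are therefore self-consistent
with the calibration generator by construction — which is exactly what
makes them useful for testing the pipeline, and exactly why passing
tests on them demonstrates correctness of the *analysis*, not fidelity
of any electromagnetic model. Real spectra additionally contain
baseline drift, wavelength-dependent noise, template scattering
backgrounds and partial endpoint drift within the saturation regime,
none of which are emulated.

SAXS profiles are generated with multiplicative Gaussian noise
(counting-statistics-like) and carry propagated uncertainties
$\sigma_I$, as reduced synchrotron data do.

## Numerical choices and degenerate inputs

* Wavelengths, lengths and spacings are nm throughout; $Q$ is stored in
  nm$^{-1}$ and Å$^{-1}$ input is converted exactly once with a
  provenance flag.
* Experimental spectra are normalized at the 350 nm anchor (nearest
  grid point within 1 nm) before comparison.
* Identical spectra passed to the crossing detector raise a
  degenerate-input error; families with any non-crossing pair report
  "no isosbestic" rather than failing.
* Sigmoid fits refuse data whose fitted upper limit does not exceed the
  lower limit; stiffness calibrations additionally require a monotone
  decreasing trend (Kendall $\tau$).
* Monte-Carlo checks in the suite use 200 replicates at fixed seeds;
  the solver-based tests use 2-nm wavelength grids and chains of 3–10
  particles, sizes at which every assertion is converged (halving the
  grid step moves peaks by <0.5 nm).

## Known limitations

* Point-dipole fidelity at sub-nm gaps, as discussed: spectra there are
  qualitative. Multipolar per-particle response, substrate contrast and
  periodic arrays are out of scope.
* The decoupling approximation ($S$ independent of particle size)
  biases $S(Q)$ for polydispersities well above the ~13% used here.
* Whether the fitted $\phi$ is a local (intra-cluster) or global volume
  fraction is not resolvable from the available information; it is
  treated as an opaque fit parameter.
* The aggregation index has no canonical definition in the source; the
  default band-integral ratio (600–700 over 500–600 nm) is recorded in
  every output, and a peak-ratio alternative is provided.
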