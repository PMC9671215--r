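---
title: "Electrostatic design and lamellar characterization of catanionic lipoplex nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic design and lamellar characterization of catanionic lipoplex nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoplexr)
```

## The problem

A single-stranded antisense oligonucleotide (a GapmeR) is a short, stiff
polyanion: ~16 bases at a 0.34 nm rise, one phosphate charge per base, a
~1 nm diameter. Packaging it into a lipid nanoparticle relies on
electrostatic condensation with a cationic lipid (a DC-cholesterol-like
amphiphile, +1 headgroup on ~0.5 nm²), and the strength of that
condensation can be tuned through the dielectric permittivity of the
solvent. This package turns the design arithmetic of that route — and the
analysis of the particles it produces — into tested functions.

## Electrostatic design model

Two lengths control everything. The Bjerrum length

$$\lambda_B = \frac{e^2}{4\pi\varepsilon_0\,\varepsilon_r\,k_B T}$$

is the distance below which Coulomb energy beats thermal energy
(`bjerrum_length()`, CODATA 2018 constants, default T = 298.15 K). The
charge spacing $l_0$ of the polyanion (0.34 nm) sets the Manning coupling
$\Gamma = \lambda_B / l_0$; above the threshold $\Gamma = 1$ a fraction

$$\theta = 1 - 1/\Gamma$$

of the backbone charge is neutralized by condensed counterions
(`manning_condensed_fraction()`, clamped to zero below threshold). In water
($\varepsilon_r \approx 80$) this gives $\lambda_B = 0.70$ nm,
$\Gamma \approx 2.1$, $\theta \approx 0.5$; at chloroform-like permittivity
($\varepsilon_r \approx 5$) the Bjerrum cage grows to ~11 nm, longer than
the whole rod, and `classify_regime()` labels the medium strongly
condensing. The regime rule (sub-critical at $\Gamma \le 1$; strongly
condensing when $\lambda_B$ spans the rod; weakly condensing otherwise) is
a deliberately coarse classifier mirroring that design narrative; the
thresholds are arguments, not constants.

The permittivity of a water/methanol/chloroform mixture is not measured
anywhere in this workflow, only bracketed by the endpoints (80/30/5). We
therefore default to linear volume-fraction mixing
(`mixture_permittivity()`), which reproduces the endpoints exactly and is
monotone and bounded; any other rule can be plugged in as a function. This
is a declared model choice, not a physical claim — nonideal mixing of
methanol/water is real but unconstrained by the available information.

Geometry and stoichiometry (`rod_geometry()`, `packing_aspect()`,
`lamellar_spacing()`, `catanionic_stoichiometry()`) are closed-form
identities. One bookkeeping subtlety is intentional: the counterion:unit
ratio by area tiling (per-unit rod area / headgroup area ≈ 2.1) and by
charge balance (1 for ±1e species) disagree, and the package returns both
rather than silently reconciling them; the adopted downstream value
(default 2, the bilayer-organized chemical formula) is explicit, and the
residual surface charge it implies is reported.

## Solvent and recipe arithmetic

Basis conversion uses $w_i = \phi_i\rho_i / \sum_j \phi_j\rho_j$ with
handbook densities 1.0/0.8/1.5 g/cm³ and is exactly invertible; mixing
ledgers assume ideal volume additivity, as protocol arithmetic in this
field invariably does. Compositions are kept at full precision and rounded
only for display.

Phase classification needs a binodal curve. The published record of this
system states only the critical composition (ca. 30% water / 15% methanol /
55% chloroform w/w), so the shipped asset
(`inst/extdata/bd_binodal_synthetic.csv`) is a synthetic piecewise-linear
boundary through that point, shaped like the classical diagram and
validated against the two protocol mixtures it must separate: the reaction
mixture (20/60/20 v/v) classifies monophasic and the demixing mixture
(30/40/30 v/v) biphasic. It is a replaceable file, and `binodal_model()`
accepts any digitized curve with the same header. Classification is a
point-in-polygon test in ternary plot coordinates, always performed on the
weight basis; points within 0.5 weight-% of the polyline are flagged
`boundary` instead of being forced to a side.

Formulation math (`moles_from_line()`, `mole_percentages()`,
`counterion_excess()`, `dose_concentration()`, `recipe_report()`) is plain
mass/molar-mass arithmetic with warnings, kept at full precision with
nearest-integer report columns. The payload monomer amount is a direct
user input rather than strands × bases, because published monomer
bookkeeping for such protocols is not always internally consistent;
`make_recipe_fixture()` carries the reference recipe (shell lipids
520/130/40/310 µg of POPC/cholesterol/DSPE-PEG/DSPE-PEG-MAN, giving
60/30/1/9 mol%, payload 1.3 µmol monomers against 3.0 µmol counterion,
40 nmol dosed in 250 µL).

## DLS cumulant analysis

`simulate_g2()` builds intensity autocorrelations by the Siegert relation
$g_2(\tau) = 1 + \beta\,|\sum_i w_i e^{-D_i q^2 \tau}|^2$;
`cumulant_fit()` inverts them by a weighted linear fit of
$\ln(g_2-1) = \ln\beta - 2\mu_1\tau + \mu_2\tau^2$, with weights
$\propto (g_2-1)^2$ and a fit window where $(g_2-1)/\beta > 0.05$ (both
configurable; the window floor and the clamp of a negative fitted $\mu_2$
to zero are documented conventions, since instrument vendors do not state
theirs). The polydispersity index is defined on the cumulant route,
$\mathrm{PDI} = 1 + \mu_2/\mu_1^2$, so 1 means monodisperse; the size-CV
variant $1 + \sigma_R/R_H$ is returned alongside as `pdi_size_cv`. Sizing
is Stokes–Einstein with the instrument defaults 633 nm, 90°, n = 1.33,
η = 0.89 mPa·s at 25 °C — arguments, not constants.

Second-order cumulant truncation biases the fitted $\mu_2$ low for broad
distributions (a fitted PDI ≈ 1.15 for a generating value of 1.18 over the
default window); the tests therefore assert exact recovery only where it
is exact (monodisperse), closeness on narrow mixtures, and strict
monotonicity of PDI in distribution width otherwise.

The log-normal generator (`lognormal_size_distribution()`) is moment
calibrated: after discretization (31 nodes over ±4σ) the diffusivity mean
and relative variance are affinely corrected so the intensity-weighted
mean diffusivity equals that of the target diameter and the relative
variance equals PDI − 1 exactly.

## Zeta potential

`zeta_from_mobility()`/`mobility_from_zeta()` implement the Smoluchowski
limit $\mu_e = \varepsilon\zeta/\eta$, with the electrophoresis-buffer
defaults $\varepsilon_r = 100$, $\eta = 10^{-3}$ Pa·s (a dilute KNO₃
suspension medium — deliberately not pure water). The ±5 mV neutrality
band in `summarize_replicates()` is chosen so that a preparation averaging
0 ± 3 mV is called neutral while one at ~44 mV is not; it is an argument.
These are bare, weakly screened potentials; at physiological ionic
strength the effective interactions are screened far below them, which is
why the neutrality call, not the absolute value, is the designed readout.

## Lamellar structure factor

The radial intensity of a multilamellar particle is modelled as

$$S(r) = B + S_0\,e^{-kr}\,\bigl|\sin\!\bigl(\tfrac{\pi r}{D(1+\delta r)}\bigr)\bigr|^{\alpha}$$

with repeat spacing $D$, radial decay $k$, lamellar dilation $\delta$ and
compaction exponent $\alpha$. Two conventions are fixed here and matter:
the dilation divides inside the sine argument, $\pi r / [D(1+\delta r)]$,
so positive $\delta$ swells the spacing outward (the stratified-corona
morphology); and the magnitude is taken before exponentiation so the model
is real for non-integer $\alpha$. The additive baseline $B$ absorbs the
nonzero background of real micrographs; $B = 0$ recovers the bare
oscillatory form.

Fitting (`fit_lamellar()`) is bounded Levenberg–Marquardt with multi-start
initialization: $\alpha \in \{1,2,4,8\}$, spacing at the spectral estimate
from `estimate_period()` scaled by {0.8, 1, 1.2}, and dilation started at
both 0 and a small positive value (24 starts). Ties break to the lowest
residual, then the lowest $\alpha$. Standard errors come from the
Jacobian-based covariance at the optimum; a failed fit returns a
non-converged result with diagnostics rather than a silent answer, and
`classify_particle()` maps it to `unclassified`.

The dense-layer thickness uses the full-width-at-half-maximum of one
$|\sin|^\alpha$ peak, $d = D\,[1 - (2/\pi)\arcsin(2^{-1/\alpha})]$, which
is $2D/3$ at $\alpha = 1$ and decreases strictly with $\alpha$
(1.41 nm at $D = 5.4$ nm, $\alpha = 8$). FWHM is one defensible
convention among several; thicknesses quoted under other conventions can
legitimately be smaller, so the label matters when comparing.

Particle typing uses dimensionless products of the fitted parameters:
compact (`A1_compact`) when $kD \le 0.05$, $\delta D \le 0.05$ and
$\alpha \ge 4$; core–shell (`A2_core_shell`) when decay or dilation is
appreciable and $\alpha > 1.5$; hollow (`B_hollow`) when the profile is
near-sinusoidal ($\alpha \le 1.5$) with negligible decay and dilation.
All thresholds are arguments.

## Synthetic data and what passing tests mean

Generators are pure functions of their parameters and a mandatory seed
(R's default Mersenne–Twister, applied without disturbing the caller's RNG
state), and every artifact carries a ground-truth record including an MD5
content hash, so reproducibility is checkable by hash equality.

The three particle presets carry the characterized archetype parameters —
compact (D = 5.4 nm, α = 8, k ≈ δ ≈ 0), core–shell stratified (D = 7.3 nm,
k = 0.05 nm⁻¹, δ > 0) and hollow (D = 5.2 nm, α = 1) — with the fields
that are generator conventions rather than measured values (amplitudes,
the core–shell δ = 0.1/D and α = 4) flagged `synthetic_choice` in the
ground-truth record. The image generator renders radially symmetric
particles with Poisson-then-Gaussian detector noise (SNR defined as peak
model amplitude over the Poisson standard deviation at the peak), scaled
so the noiseless peak sits at 60% of dynamic range.

Problem sizes used by the validation studies: radial profiles over six
repeat periods at 0.25 nm steps, 100 seeded replicates per preset at peak
SNR 10 for the recovery/classification study; 256² px synthetic images;
200-channel correlograms with 25–50 seed replicates for the DLS studies.
At those settings the spacing recovery error is well under 5% in the
median and classification is correct in ≥95/100 replicates per preset.

What passing does not show: the synthetic images are radially symmetric,
noise-stationary and single-particle — real micrographs have stain
granularity, defocus, sectioning geometry, overlapping particles and
profile paths that are not diameters. The generators validate the
estimators, not the microscope.

## Known limitations

- No Debye–Hückel/Poisson–Boltzmann screening: the design rules are
  zero-added-salt Manning arithmetic.
- The binodal asset is synthetic; quantitative phase work needs a
  digitized experimental curve.
- Cumulant analysis is second order; strongly polydisperse or multimodal
  samples need inverse-Laplace methods out of scope here.
- The structure-factor fit treats intensities as given (plus baseline); no
  detector transfer function or stain-chemistry model is applied.
- Dense-layer thickness is convention-bound (FWHM); compare like with
  like.
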