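# lipoplexr

Physicochemical design and characterization calculators for catanionic
lipoplex nanoparticles — antisense-oligonucleotide (GapmeR) payloads
condensed by a cationic cholesterol derivative and assembled into lipid
nanoparticles in tunable water/methanol/chloroform (Bligh–Dyer) solvents.
It is written for formulation scientists who want the desk arithmetic of
such a synthesis to be reproducible, testable code rather than a lab
notebook, and for microscopists analyzing the resulting multilamellar
particles.

The package covers four layers of that workflow:

1. **Electrostatic design.** The Bjerrum length
   λ_B = e²/(4π ε₀ ε_r k_B T), the Manning coupling Γ = λ_B/l₀ of a charged
   rod with inter-charge spacing l₀, and the condensed counterion fraction
   θ = 1 − 1/Γ (zero below the Γ = 1 threshold). A mixing rule maps a
   ternary solvent composition to an effective permittivity, so the
   condensation regime can be steered by solvent choice.
2. **Solvent and recipe arithmetic.** Volume/weight basis conversion
   (w_i = φ_i ρ_i / Σ φ_j ρ_j), ideal mixing ledgers,
   monophasic/biphasic classification against a binodal curve, lever-rule
   phase fractions, and mole/mole-percent bookkeeping for the synthesis
   recipe, including counterion stoichiometric excess and payload dosing.
3. **Instrument analysis.** Dynamic light scattering by second-order
   cumulant analysis (μ₁ = D̄q², PDI = 1 + μ₂/μ₁², Stokes–Einstein sizing
   D̄ = k_B T / 6πηR_H), and Smoluchowski zeta-potential conversion
   μ_e = εζ/η with replicate aggregation and a neutrality call.
4. **Lamellar ultrastructure.** The package's core: fitting the
   damped-oscillatory lamellar structure factor

   S(r) = B + S₀ e^(−kr) |sin(πr / D(1 + δr))|^α

   to radial intensity profiles extracted from TEM images (spacing D, decay
   k, dilation δ, compaction α), with multi-start bounded least squares,
   FWHM dense-layer thickness, and rule-based particle typing
   (compact / core–shell / hollow).

Seeded generators (`make_lamellar_image()`, `make_noisy_profile()`,
`make_dls_dataset()`, `make_zeta_replicates()`) emulate the instrument data
with known ground truth, so every analysis stage is testable end to end
without external data.

## Worked example

```r
library(lipoplexr)

# Where does counterion condensation happen?
condensation_assessment(solvent_medium(80))   # water
#> Condensation: lambda_B = 0.701 nm, Gamma = 2.06, theta = 0.51 [weakly_condensing]
condensation_assessment(solvent_medium(5))    # chloroform-rich phase
#> Condensation: lambda_B = 11.209 nm, Gamma = 32.97, theta = 0.97 [strongly_condensing]
```

In water the Bjerrum cage (0.70 nm) spans only two nucleotides, so roughly
half the backbone charge is neutralized (θ ≈ 0.5); at chloroform-like
permittivity the cage (11.2 nm) exceeds the whole 5.4 nm oligonucleotide
rod and condensation is essentially complete — the design rationale for
transferring the lipoplex into the organic Bligh–Dyer phase.

```r
# Fit a noisy synthetic compact-particle profile (true D = 5.4 nm, alpha = 8)
prof <- make_noisy_profile(lamellar_preset("A1"), snr = 10, seed = 42)$profile
fit <- fit_lamellar(prof)
fit
#> Lamellar fit: D = 5.402 nm, alpha = 7.58, k = 0.0024 1/nm, delta = 0.0000 1/nm,
#>   S0 = 1.05, baseline = 0.0934 (residual 0.682, 24 starts)
classify_particle(fit)$label
#> [1] "A1_compact"
dense_layer_thickness(fit$params$D, fit$params$alpha)
#> [1] 1.45   # nm, FWHM convention

# DLS of the pellet preset (172 nm, PDI 1.18 ground truth)
cumulant_fit(make_dls_dataset(preset = "pellet", noise_sigma = 0.002,
                              seed = 42)$trace)
#> Cumulant fit: D = 2.848e-12 m^2/s, diameter = 172.3 nm, PDI = 1.150 (n = 181)
```

The fitted spacing lands within 0.1% of the generating value at a peak
signal-to-noise ratio of 10, and the particle is correctly typed as a
compact multilamellar archetype; the DLS cumulant fit recovers the
hydrodynamic diameter within a fraction of a percent (the fitted PDI sits
slightly below the distribution value, the usual truncation bias of a
second-order cumulant expansion on a finite fit window).

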