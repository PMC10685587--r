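# lamellar

Analysis of oriented lipid-multilayer stacks studied by neutron
diffraction under osmotic stress, and of the z-resolved density profiles
produced by matched molecular-dynamics simulations.

Membrane stacks of saturated-chain lipids — e.g. phosphatidylcholine
(DPPC) versus its phosphorus-free betaine analogue (DP-DGTS), which
microalgae use to replace PC under phosphate starvation — differ in
bilayer thickness, bending rigidity, and inter-membrane repulsion.  This
package implements the complete quantitative chain with which such
differences are established from lamellar diffraction:

* **Reduction** — Bragg's law d-spacings and corrected structure factors
  |F<sub>n</sub>|² = C<sub>abs</sub> C<sub>Lor</sub> I<sub>n</sub>, with
  C<sub>abs</sub> = α/(1 − e<sup>−α</sup>), α = 2µt/sin θ and
  C<sub>Lor</sub> = sin 2θ; humidity → osmotic pressure via the Kelvin
  relation Π = −(k<sub>B</sub>T/v<sub>w</sub>) ln RH.
* **Phasing & NSLD synthesis** — exhaustive sign search under
  centrosymmetric physical constraints, then
  ρ(z) = (2/d) Σ ν<sub>n</sub>|F<sub>n</sub>| cos(2πnz/d).
* **Bilayer geometry** — headgroup centre-to-centre thickness d_b from a
  mirrored-Gaussian fit; water layer d_w = d − d_b with quadrature errors.
* **Hydration repulsion** — exponential fits Π = Π₀ e<sup>−d_w/λ_w</sup>
  in log-pressure space, and the classical beam-theory cube law
  κ ∝ d_b³.
* **Smectic mechanics** — the Caillé parameter
  η = πk<sub>B</sub>T/(2d²√(κB/d)) and de Gennes parameter
  Λ = √(κ/(Bd)); an exact Gaussian sampler of the discrete smectic
  Hamiltonian with kinematic Bragg-sheet scattering, and a fitting
  procedure that recovers (η, Λ) → (κ, B) from the first two sheets.
* **MD profile analytics** — water polarization profiles, per-leaflet
  headgroup dipole moments, Gibbs–Duhem osmotic pressures
  Π = −(µ − µ₀)/v_w⁰, truncated-Fourier NSLD from component densities,
  and headgroup-orientation medians.
* **Forward generators** — synthetic bilayer SLD models, peak tables,
  pressure–distance curves, Bragg-sheet maps and charge-density profiles,
  each with a recorded ground truth, so the whole pipeline is validated
  closed-loop.

## Worked example

A synthetic 4-order fluid-phase peak table at the 8% D2O contrast-match
point, pushed through the full chain:

```r
library(lamellar)
cond  <- diffraction_condition(relative_humidity = 0.96, d2o_fraction = 0.08)
model <- make_sld_model(d = 50, z_head = 18.05)      # true d_b = 36.1 A
g  <- gen_peak_table(model, cond, n_orders = 4, noise_fraction = 0.02, seed = 42)
ds <- lamellar_dataset(g$peaks[1:4], cond, "fluid")
fs <- assign_phases(structure_factors(ds))
fs
#> structure factors (fluid phase), d = 50.00 A:
#>   n=1  |F| = 39.05 (-)
#>   n=2  |F| = 11.37 (-)
#>   n=3  |F| = 12.35 (+)
#>   n=4  |F| = 12.82 (-)
geom <- fit_bilayer_thickness(synthesize_profile(fs))
geom
#> bilayer geometry: d = 50.00 A, d_b = 36.56 +/- 0.88 A (rms 0.0199)
water_thickness(geom$d, geom$d_b, ds$d_err, geom$d_b_err)$d_w
#> [1] 13.44
```

The assigned signs (−, −, +, −) are the canonical fluid-phase PC pattern,
and the fitted d_b lands within the Fourier-truncation tolerance of the
generator's 36.1 Å.  A hydration-repulsion fit on a seeded 12-point
pressure–distance curve (5% log-normal noise, true λ_w = 7.7 Å):

```r
fit_hydration_decay(gen_pressure_curve(pi0 = 1e9, lambda_w = 7.7,
                                       n_points = 12, noise_fraction = 0.05,
                                       seed = 7))
#> hydration fit (fluid phase, 12 points): Pi0 = 9.45e+08 Pa, lambda_w = 8 +/- 0.21 A
```

Smectic mechanics, forward and inverse:

```r
caille_parameter(22, 1.5e6, 60, 323.15)    # eta  = 0.0393
degennes_parameter(22, 1.5e6, 60, 323.15)  # Lambda = 33.0 A
beam_theory_kappa(14, 36.1, 40.9)          # 20.4 kBT (cube-law estimate)
```

A thin command-line wrapper over the same functions lives in
`inst/cli/lamellar.R` (`simulate`, `reduce`, `phase`, `reconstruct`,
`forces`, `mdprof` subcommands).

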