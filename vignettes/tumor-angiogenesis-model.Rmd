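---
title: "The coupled tumor-growth / angiogenesis model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled tumor-growth / angiogenesis model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiophase)
```

# The model

`angiophase` simulates a solid, non-invasive lesion interacting with the
vasculature of the surrounding tissue. It is a *hybrid* model: tissue-scale
quantities are continuum fields, while the migratory tip endothelial cells
(TECs) that lead new capillary sprouts are discrete agents, stitched into
the continuum through template functions.

## Continuum fields

Four fields live on a rectangular quarter domain `Ω_q` (two edges are
symmetry planes, two are outer tissue boundaries; all carry zero-flux
conditions):

* `φ ∈ [0, 1]`, the tumor phase field. Its free energy is
  `Ψ_φ = ½λ_φ²|∇φ|² + g(φ) + m(σ)h(φ)` with the double well
  `g = φ²(1−φ)²`, the interpolant `h = φ²(3−2φ)` and the tilting function
  `m(σ) = −(2/(3.01π)) arctan(15(σ − σ_hv))`. Because `|m| < 1/3.01 < 1/3`,
  both bulk states remain local minima at every nutrient level: tumor and
  host tissue are metastable, and the nutrient decides which is *globally*
  preferred. Gradient dynamics
  `∂φ/∂t = M_φ(λ_φ²Δφ − μ_φ)`, `μ_φ = g′ + m h′`, make the free energy
  non-increasing when `σ` is frozen.
* `σ ∈ [0, 1]`, a generic vital nutrient:
  `∂σ/∂t = ∇·(D_σ∇σ) + V_pc(1−σ) c H(c) S − V_uT σφ − V_uH σ H(1−φ)`.
  `H` is a smoothed step, so `cH(c)` marks the capillary interior; tumor
  uptake is ten-fold the host uptake. `S ∈ (0,1]` (next section) throttles
  delivery as the network densifies.
* `c ∈ [−1, 1]`, the capillary phase field, a Cahn–Hilliard equation with
  endothelial (stalk-cell) proliferation:
  `∂c/∂t = ∇·(M_c∇(μ_c(c) − λ_c²Δc)) + B_p(f) c H(c)`, `μ_c = c³ − c`,
  `B_p(f) = B_p min(f, f_p)`.
* `f ∈ [0, 1]`, tumor angiogenic factor (TAF), the net pro-angiogenic
  signal: `∂f/∂t = ∇·(D_f∇f) + φ(1−f)G(σ) − B_u f c H(c)` with secretion
  `G(σ) = G_amp exp(−125(σ − (σ_nh+σ_hv)/2)²)` peaked mid-hypoxia: necrotic
  tissue cannot signal and well-fed tissue does not.

## Network functionality

The vasculature is additionally book-kept as a list of segment lengths: the
parent vessel (one fixed segment the width of the quarter domain) plus one
sprout per activated TEC, whose length is the tip's accumulated migration
arc. The statistic `S = l_max / Σ l_i` is 1 for a single vessel and decays
as sprouts are added — a deliberately crude summary of the observation that
dense, tortuous tumor-induced networks perfuse poorly. A sprout opens with
length `R` (the imprinted cell body) so lengths are always positive, and
keeps its length when it closes. An image-based oracle
(`skeleton_lengths()`: threshold, Zhang–Suen thinning, branch partition) can
cross-check the tracked lengths to topology-level accuracy (~15%); thinning
is implemented in the package because no installed image package provides
it.

## Tip endothelial cells

TECs are circular agents of radius `R`, activated at grid nodes where
`c ≥ c_act` (on a vessel) and `f ≥ f_act` (enough TAF), provided no active
TEC — including mirror images across the two symmetry edges — lies within
the Dll4 effective distance `δ₄`. This distance is the model's whole account
of Dll4/Notch lateral inhibition; shrinking it (the `dll4_blockade`
scenario, `δ₄ = 55` instead of 80) admits more tips and denser but less
functional networks. When several nodes qualify, exactly one is chosen
uniformly at random — the model's only stochastic operation, driven by a
dedicated seeded stream so runs are bit-reproducible.

Active tips move with `v = χ (∇f/|∇f|) J(φ)`,
`J(φ) = 0.45[tanh(50(0.5−φ))+1] + 0.1`, i.e. at `χ` through stroma and a
tenth of that inside the lesion. Each step the tip imprints
`max(c, tanh((R−r)/ε))` within `3R` of itself, leaving a contiguous trail
that the proliferation term then sustains. Once a tip has migrated more than
`4R` of arc from its parent vessel it probes `c` at filopodia sample points;
a positive sample redirects the cell straight at the detected capillary
until it comes within `R` of a foreign vessel node and anastomoses. Cells
deactivate on anastomosis, on reaching a domain edge, or after ten
consecutive steps with `f < f_act` at their centre.

Choices the model statement leaves open were fixed as follows, and are
config-exposed:

* **Filopodia geometry.** Sixteen samples: radii `{2R, 4R}` on rays every
  45°, skipping rays within 60° of the reversed velocity (the trailing
  cone). This probes "nearby" tissue at filopodia reach without staring at
  the cell's own sprout.
* **Self-exclusion.** Samples (and anastomosis candidates) within `1.5R` of
  the cell's own trail are ignored, so a sprout neither detects nor fuses
  with itself. The trail window is the stretch between `2R` and `8R` of arc
  behind the tip: the freshest stretch must be excluded from the exclusion,
  since every point near the tip is trivially near the path's end and
  counting it would veto all anastomoses. Conversely the tip's own template
  cannot raise `c` to `c_act` beyond `R − ε·atanh(c_act) ≈ 2.5` from its
  centre, so anastomosis candidates are sought in the annulus between that
  body radius and `R`, where a `c ≥ c_act` node necessarily involves foreign
  vasculature.
* **Deactivation hysteresis.** The instantaneous reading of the activation
  conditions flickers as fields fluctuate; requiring ten consecutive
  sub-threshold steps avoids spurious deactivation.
* **Re-activation.** A closed sprout may later host a new TEC; nothing but
  the three activation conditions governs activation.

# Parameters

`model_parameters()` returns the full non-dimensional set; lengths scale by
`L = 1.25 µm` per unit and times by `T = 1562.5 s` per unit (one day is
55.296 time units).

| symbol | default | meaning |
|---|---|---|
| `M_phi`, `lambda_phi` | 0.3, 22 | tumor mobility, interface constant |
| `D_sigma` | 30 | nutrient diffusivity |
| `V_pc` | 1 | capillary nutrient production |
| `V_uT`, `V_uH` | 6e-3, 6e-4 | tumor / host nutrient uptake |
| `sigma_nh`, `sigma_hv` | 0.2, 0.4 | necrotic–hypoxic, hypoxic–viable thresholds |
| `f_p` | 0.3 | proliferation saturation TAF level |
| `M_c`, `lambda_c` | 1, 1 | capillary mobility, interface constant |
| `B_p` | 1.401 | endothelial proliferation rate |
| `R` | 4 | TEC radius (5 µm) |
| `c_act`, `f_act` | 0.9, 1e-3 | TEC activation thresholds |
| `chi` | 7.28 | chemotactic speed (≈ 0.5 mm/day) |
| `delta4` | 80 | Dll4 exclusion distance (100 µm) |
| `D_f`, `B_u` | 100, 6.25 | TAF diffusivity, vessel uptake |

Auxiliary constants: the Heaviside smoothing `eps_H = 0.1` (so `cH(c)`
approximates the positive part of `c`), the template width
`eps_template = 1`, and the TAF secretion amplitude
`G_amp = 0.02/√(2π) ≈ 7.98e-3`. The amplitude is genuinely uncertain — the
model is insensitive to its exact value because `f` saturates in the
hypoxic annulus and the activation threshold `f_act` is three orders of
magnitude smaller — and it is therefore an explicit parameter rather than a
hard-coded constant.

# Numerics

* **Space.** Cell-centred grids, 5-point stencils, mirror boundaries. The
  mirror Laplacian is diagonalized exactly by the type-II discrete cosine
  basis; the constructor caches the (orthonormal) basis matrices, and each
  implicit solve is two dense matrix products and a pointwise division —
  exact for the discrete operator, so the Cahn–Hilliard update conserves
  mass to machine precision and symmetric data stay symmetric.
* **Tumor step.** Lie splitting: the pointwise reaction ODE is advanced
  with explicit substeps (count chosen so each substep is well inside the
  stability limit of the stiffest linearization, `|μ_φ′| ≤ 4`), then the
  linear diffusion is solved implicitly. A single stabilized IMEX sweep was
  rejected because its stabilizer damps front motion by a factor
  `~(1 + dt M_φ s)` at the largest steps, biasing exactly the long-horizon
  front positions the package reports.
* **Nutrient / TAF steps.** The reactions are linear in the unknown with
  frozen coefficients and are integrated *exactly* (exponential update),
  which provably keeps `σ, f ∈ [0, 1]`; diffusion is then implicit. For
  this to hold, `cH(c)` is clamped at zero where it appears as a
  production/uptake coefficient (it is a numerical surrogate for "inside a
  vessel"; without the clamp its slight negativity outside vessels would
  act as a spurious source).
* **Capillary step.** Convexity splitting: biharmonic term and a stabilizing
  `a Δc` (`a = 2 ≥ max|μ_c′|` on the well interval) implicit, double-well
  remainder and proliferation explicit.
* **Adaptive dt.** Bounds `[1e-4, 5]`; halve on solver failure or when the
  max-norm field change exceeds `5e-2`, grow by 1.2 below `5e-3`, and cap
  so no TEC moves more than `R/2` per step (keeping imprinted trails
  contiguous and the agent/continuum coupling resolved).
* **Guards.** `validate_field_state()` enforces the representation
  contract: `σ, f` within `[0,1]` (roundoff-clipped), diffuse-interface
  overshoot of at most 0.05 on `φ` and `c`. During a run the driver applies
  a wider blow-up envelope (`|c| ≤ 1.5`, `φ ∈ [−0.25, 1.25]`) because the
  proliferation term can push `c` to ≈1.2 transiently when TAF is high;
  this is genuine model behaviour, not a numerical failure.

# Scenarios and the initial state

`build_initial_state()` generates every initial condition programmatically:
a quarter-disc tumor of radius 625 µm centred where the two symmetry edges
meet (necrotic core at 45% of the radius with `σ = 0`), a 25 µm capillary
strip along the bottom outer edge with `σ = 1`, background `σ = 0.45`,
`f = 0`. Interfaces are seeded as `tanh` profiles (widths tied to `λ_φ/10`
and `λ_c`) rather than jumps to avoid first-step stiffness; the strip's
`σ = 1` is an initial condition only — afterwards the production term alone
sustains the capillary nutrient level. The top vessel of the full-tissue
picture is the mirror image of the bottom one and needs no separate source.
These initial data emulate a lesion at the diffusion-limited size with an
idealized straight parent vessel; they do not attempt capillary tortuosity,
heterogeneous host perfusion, or mechanical stress, so conclusions about
real tissue rest only on the model mechanisms, not on geometric realism.

Modes: `avascular` (freezes `c` and `f`, never activates TECs, pins
`S = 1`; default horizon 1054 days), `vascular` (everything on; 5.1 days),
`dll4_blockade` (`δ₄ = 55`; 5.1 days), `small_spheroid` (tumor radius ÷ 3).
The per-step order is: nutrient, tumor, TAF, capillaries, TEC
motion/imprint/filopodia/anastomosis, at most one activation, network
update.

# Problem sizes

The production grid is 512×396 (≈2.6 µm spacing, resolving the `λ_c = 1`
vessel walls marginally and the `λ_φ = 22` tumor interface comfortably).
The test suite and the acceptance script use desk-scale grids chosen as the
coarsest that keep the observables' grid sensitivity within ~2%: 128×99 for
the long avascular run, 256×198 for the single full vascular run, 192×148
for the vascular growth statistic (three seeds), and 128×99 with a 4.6-day
horizon for the five paired Dll4 comparisons. The unit tests run on 64×48
and smaller.

# Time scales and known limitations

The tilted-well front speed of the tumor equation has the closed form
`v = M_φ m(σ) · 3√2 λ_φ` for a flat interface (the package's 1D oracle test
verifies the implementation against it). With the default
`M_φ = 0.3, λ_φ = 22` this is ≈ 28·m per time unit — several hundred µm/day
at the tilt levels (`m ≈ 0.2–0.3`) that the nutrient model actually
produces around the lesion once the background nutrient is consumed. Two
consequences follow with the defaults:

* the avascular lesion regresses completely within a few simulated days
  (the day-1054 equivalent-radius observable evaluates to 0), and
* in the vascular scenario the lesion is gone before the sprouts — which
  need about three days of TAF transport before the first activation —
  reach it, so the renewed-growth stage of the area curve does not occur.

No single mobility value reconciles a ten-percent early transient occurring
within days with a years-long regression: the front speed is linear in `m`,
and those two behaviours would require effective speeds differing by two
orders of magnitude at comparable tilt. Reproducing slow, dormancy-like
regression therefore requires either a much smaller tumor mobility (at the
cost of suppressing the early transient) or an interface pinned to the
`σ = σ_hv` level set by a mechanism outside this model. The package keeps
the tabulated defaults, reports what they produce, and leaves `M_phi`
config-exposed for users who want to explore the slow-interface regime.
The nutrient side is unaffected: the quasi-steady hypoxia distance
(`≈ √(D_σ/V_uH) · ln(1/σ_hv)` from the vessel, ~220–250 µm measured) and
the ~3-day onset of TEC activation are robust observables of the default
set.

Other limitations: two-dimensional only; no blood flow, vessel radii, or
pruning; stalk-cell dynamics are wholly continuum; the Dll4 pathway is a
single exclusion distance; anastomosis closes a sprout's growth but does not
merge segment bookkeeping (the oracle cross-check guards the resulting `S`
against drift); and the Zhang–Suen skeleton oracle under-measures branch
ends by about the vessel half-width, compensated by an endpoint-clearance
correction.

# Determinism and outputs

All randomness flows through one seeded stream consumed exclusively by the
activation tie-break, so equal seeds give bit-identical series. Runs write
plain-text outputs: an exactly round-trippable CSV time series (17
significant digits), a TEC event log, the segment table, a YAML manifest,
and legacy ASCII VTK image snapshots of the four fields.
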