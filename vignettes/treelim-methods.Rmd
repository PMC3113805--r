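---
title: "Methods: the resource-limitation model behind treelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the resource-limitation model behind treelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treelim)
```

## The model

`treelim` is a steady-state calculation, not a simulation: long-term
annual-mean meteorology goes in, a maximum sustainable tree height
comes out. One idealized, species-independent tree is used everywhere;
its size-dependent features come from power-law scaling relations
(`scaling_law` objects), each a `(prefactor, exponent)` pair with unit
metadata. Three water flow rates, all in liters/day, are compared as
functions of height *h*:

* **Required flow `Q0(h)`.** The basal metabolic requirement is an
  empirical two-regime power law in trunk diameter `D` (cm), with a
  hard switch at a crossover diameter; `D` itself comes from inverting
  the height–diameter law `h = c·D^(2/3)` (elastic similarity, valid
  for large trees; small-tree curvature corrections are deliberately
  out of scope). `Q0` depends on size only, never on the environment.

* **Evaporative flow `Qevap(h, env)`.** The canopy is treated as one
  big leaf with effective exchange areas proportional to its total
  one-sided leaf area `LA`: `A_X = c_X · LA` with defaults `c_L = 2`
  (two-sided thermal emission), `c_H = 2` (two-sided convection),
  `c_E = 1` (hypostomatous evaporation). Absorbed radiation is

  `R_abs = S · α · (1 − e^{−k·LAI}) · A_proj + ε σ T_air⁴ · A_L`,

  a Beer–Lambert closure over the projected canopy area plus ambient
  longwave loading at air temperature. The Beer–Lambert form is this
  package's own closure for partially transparent small canopies; it
  reproduces the standard optically-deep limit `α·S·A_proj` once
  `k·LAI ≳ 5`. Including the ambient longwave term makes the energy
  budget physically closed: with no sun and saturated air the canopy
  sits exactly at air temperature and evaporation is exactly zero.
  Canopy temperature `T_L` solves

  `R_abs = A_L ε σ T_L⁴ + A_H c_p g_Ha (T_L − T_air) + A_E λ g_v (e_s(T_L) − e_a)/p_a`,

  with Tetens saturation `e_s(T) = 0.6108·exp(17.27T/(T+237.3))` kPa,
  molar heat capacity `c_p = 29.3 J mol⁻¹ K⁻¹`, and a constant latent
  heat `λ = 44.0 kJ mol⁻¹` (all overridable via `energy_constants()`).
  Conductances follow standard leaf-microclimate forms: boundary-layer
  `g_va = 1.4·0.147·√(u/d)` and `g_Ha = 1.4·0.135·√(u/d)` for wind `u`
  and characteristic leaf dimension `d`; stomatal conductance linear in
  stomatal density through a reference pair (the simplest relation
  consistent with density as the controlling trait; densities are
  leaf-side averages, and the linear reference-pair form is also how a
  two-sided counting convention would be absorbed); total vapor
  conductance is the series combination. The evaporative molar flux
  `E = g_v (e_s(T_L) − e_a)/p_a` converts to liters/day through the
  molar mass and density of water over `A_E`.

* **Available flow `Qp(h, env)`.** Precipitation falling on the disc
  above the lateral root extent, times a root absorption efficiency in
  [0, 1]. Interception only: runoff, pooling, storage and snow are
  explicitly not modeled.

A tree functions only while `Q0 ≤ Qevap ≤ Qp`. The predicted maximum
height is the upper edge of the feasible region attached to the
smallest searched height — a tree must grow through every intermediate
size, so feasible "islands" detached from the seedling region are
reported as diagnostics but never used.

### Solver modes

`max_height()` offers two modes. `mode = "both"` enforces the full
chain and labels the binding constraint `"metabolic"` or `"water"`;
`mode = "metabolic_only"` checks only `Qevap ≥ Q0`, the practical
shortcut appropriate once the root absorption efficiency has been
calibrated so that the supply curve tracks the requirement curve. The
exported default is `metabolic_only` for single-site prediction, but
the analyses in this package that compare regimes (temperature shifts,
trait optimization, the acceptance script) use `"both"`, because their
scientific content — warming lowers the ceiling where water binds;
trait optima trade energy capture against water use — lives in the
water constraint.

## Parameters and defaults

All defaults are this package's calibration for an average tree; they
are versioned in `inst/extdata/allometry-default.yaml`, logged by every
CLI run, and refittable from data with `fit_scaling_law()`.

| Quantity | Default | Units | Rationale |
|---|---|---|---|
| height vs diameter | `2.0·D^(2/3)` | m from cm | elastic similarity; 43 m at D = 1 m |
| basal flow, small trees | `0.00266·D^2.5` | L/day from cm | steeper sapling regime, continuous at crossover |
| basal flow, large trees | `0.006·D^2.2` | L/day from cm | ~46 L/day at D = 58 cm; requirement well below total transpiration |
| crossover diameter | 15 | cm | regime switch; laws agree to 0.1% there |
| canopy radius | `0.1·h^1.1` | m from m | 4.2 m crown radius at h = 30 m |
| canopy depth | `0.5·h` | m from m | crown occupies upper half of the stem |
| root radius | `0.2·h^1.1` | m from m | lateral roots reach ~2 crown radii |
| leaf count | `50·D^2` | count from cm | with leaf area, LAI 2–8 over 10–60 m |
| single leaf area | 0.0015 | m² | 15 cm², mid-range across taxa |
| stomatal density | 200 | mm⁻² | leaf-side average |
| reference g_s | 0.045 at 200 mm⁻² | mol m⁻² s⁻¹ | annual-mean *effective* conductance: annual transpiration of a 30 m tree ≈ 120 L/day ≈ 0.7 m/yr over its footprint, matching real forest water use; an instantaneous midday maximum would overstate annual flow several-fold |
| leaf dimension | 0.05 | m | mid-range broadleaf/needle cluster |
| shortwave absorptivity | 0.8 | — | standard green leaf |
| extinction coefficient k | 0.5 | — | spherical leaf-angle canopy |
| emissivity | 0.97 | — | vegetation longwave |
| soil / deep-canopy reflectance | 0.30 / 0.15 | — | representative bare soil and closed canopy |
| root absorption efficiency | 0.4 | — | single calibratable scalar per run |

The junction of the two basal-flow laws is a hard switch; construction
warns if the laws disagree by more than 5% at the crossover, since two
independently fitted empirical regimes should nearly agree where they
meet.

## The synthetic-environment generator

`environment_grid_spec()` + `generate_environments()` emulate site
climatologies so every stage is testable without downloads. Transect
mode interpolates jointly ordered gradients — first site wettest and
coolest (default 2.5 m/yr, 4 °C, RH 0.75, 170 W/m²), last driest and
hottest (0.25 m/yr, 28 °C, RH 0.25, 330 W/m²) — spanning boreal-moist
through desert conditions so both energy- and water-limited regimes
occur; independent mode draws each variable uniformly under a fixed
seed. The generator reproduces the *structure* of real climatologies
(long-term means, wet-cool/arid-hot covariation) but none of their
texture: no elevation effects, no seasonality, no spatial correlation,
no humidity–radiation coupling. Passing tests therefore demonstrate
internal correctness and the model's qualitative regime logic, not
validated skill against observed tree heights, which requires paired
tree–station data (station pairing in the calibration literature keeps
sites within 100 m elevation and 4 km distance).

## Numerical choices

* **Canopy temperature.** The loss side of the budget is strictly
  increasing in `T_L`, so the root is unique. The solver asserts a
  sign change over `[T_air − 40, T_air + 40] °C`, then runs Newton
  with the analytic derivative from `T_air`, each step safeguarded by
  the shrinking bracket (bisection fallback), to a residual below
  `1e-9·max(1 W, R_abs)`, at most 100 iterations; non-convergence is
  an error carrying the worst residual. Starting at `T_air` makes the
  dark-saturated equilibrium exact in floating point.
* **Height search.** 400-point log-spaced scan over 0.5–150 m
  (seedling to the tallest known trees; log spacing resolves the
  small-tree end where the curves are steep in relative terms), then
  bisection of the bracketing interval to 0.01 m. Feasibility at 150 m
  is reported as `binding_constraint = "cap"` — the model then puts no
  ceiling below the domain top. Infeasibility at 0.5 m is data, not an
  error: arid sites genuinely support no trees in-model.
* **Trait optimization.** 64-point coarse scan over the bounds, then
  golden-section refinement only inside the bracketing interval of the
  scan maximum (unimodality is not assumed globally), to 0.1 mm⁻² for
  stomatal density and 1e-4 m for leaf size; ties break toward the
  lower trait value. Degenerate bounds (min = max) return that value.
* **Degenerate inputs.** Zero wind gives zero boundary-layer
  conductance (radiative equilibrium still solvable); zero stomatal
  density shuts the vapor path and forces `Qevap = 0`; constant laws
  (exponent 0) refuse inversion; the strict CSV reader itemizes every
  offending row rather than failing on the first.
* **Units.** Heights/radii in m, diameters in cm, flows in liters/day
  at all module boundaries; a year is 365.25 days; every conversion is
  centralized in one file.

## Design decisions and known limitations

* **Regime dependence of the trait trends.** The optimal stomatal
  density declines monotonically with temperature on any transect we
  generate. The optimal *leaf size* is a weaker signal (a few percent
  of `h_max`) whose direction depends on the binding regime: in
  water-bound climates the optimum moves from large leaves (cool) to
  small leaves (hot) — small leaves stay coupled to air temperature
  and waste less water when the canopy is radiation-loaded — but in
  energy-limited (wet, dim) climates the preference can reverse. The
  monotone declining trend should therefore be read as the model's
  prediction for water-limited transects, and that is the setting in
  which the package's tests assert it.
* **Warming response.** `Qevap` increases with air temperature (larger
  saturation slope and vapor deficit), so warming lowers the ceiling
  where water binds and raises it where energy binds. Mean responses
  reported by the acceptance script are computed on a water-limited
  transect, where the response is uniformly negative and of order
  −14% per +2 °C with the shipped calibration.
* **Over-prediction in wet climates.** Wet, mild sites can be feasible
  all the way to the 150 m cap. Real stands there are limited by
  competition and disturbance, which this steady-state single-tree
  model does not represent.
* **Annual means only.** Diurnal and seasonal cycles, storm-scale
  interception, CO₂ effects on stomata, within-canopy temperature
  profiles, and species-specific allometries are all out of scope.
* **Sensitivity analyses.** `temperature_sensitivity()` shifts air
  temperature only (relative humidity held fixed, so absolute humidity
  rises with the shift); `exponent_sensitivity()` perturbs one
  exponent at a time by a percentage and reports the median percent
  height change (or median signed relative error when observations
  are supplied).

## Problem sizes used by the test suite

The standing tests solve the energy budget at 1,000 random
environment × height combinations for closure, check the Newton
temperature against a 0.001 K grid scan at 50 environments, recover 20
closed-form crossings, verify the bisection against a 1 mm brute-force
scan at 10 environments, compare the golden-section trait optimum with
a 1,024-point brute-force scan at 3 environments, and evaluate both
trait optima along an 8-site water-limited transect. The whole suite
runs in about a minute on one core.
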