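# treelim

How tall can a tree get in a given climate? `treelim` answers that with
a steady-state, species-independent model aimed at ecophysiologists and
ecosystem modelers: allometric scaling laws describe an average tree of
height *h* (trunk diameter, canopy and root geometry, leaf number), and
three water flow rates derived from those laws are compared.

- **Q0(h)** — the basal metabolic requirement: the minimum internal
  flow needed to support metabolism, an empirical two-regime power law
  in trunk diameter, independent of the environment.
- **Qevap(h, env)** — the evaporative flow: trees are passive solar
  pumps, so the internal flow equals canopy evaporation, obtained by
  solving the canopy energy budget
  `R_abs = A_L εσT_L⁴ + A_H c_p g_Ha (T_L − T_air) + A_E λ g_v (e_s(T_L) − e_a)/p_a`
  for canopy temperature `T_L`, with each effective area `A_X`
  proportional to total one-sided leaf area.
- **Qp(h, env)** — the available flow: precipitation intercepted over
  the lateral root footprint, times a root absorption efficiency.

A tree functions only while `Q0(h) ≤ Qevap(h) ≤ Qp(h)`; the largest
height at which the chain still holds — found by a log-spaced scan and
bisection of the first crossing — is the predicted local maximum tree
height, and the crossed curve says whether the site is energy-limited
("metabolic") or water-limited ("water"). The same machinery yields the
height–albedo curve of the canopy–soil system, environment-optimal
stomatal density and leaf size, and sensitivity of predictions to
temperature shifts and to individual scaling exponents. A synthetic
site-climatology generator spans wet/cool to arid/hot regimes so the
whole pipeline runs without external data.

## Worked example

```r
library(treelim)

env <- met_environment(precipitation = 0.8,      # m/yr
                       air_temperature = 16,     # degrees C
                       relative_humidity = 0.45,
                       wind_speed = 3,           # m/s
                       solar_radiation = 260,    # W/m^2
                       site_id = "dry_foothills")
res <- max_height(env, trait_set(), water_budget_params(),
                  allometry_config(), mode = "both")
res
#> <max_height_result> h_max = 34.75 m (water-bound, mode both)

flow_curves(env, trait_set(), water_budget_params(), allometry_config(),
            h_grid = c(5, 15, 30, 60))
#>   height q_required q_available q_evaporative
#> 1      5     0.0826         3.8         0.846
#> 2     15     4.6329        42.6        22.264
#> 3     30    45.6302       195.6       174.640
#> 4     60   449.4190       898.9      1372.430
```

At this semi-arid site the model predicts a 34.8 m ceiling, set by
water: between 30 and 60 m the evaporative flow (liters/day) overtakes
what the root footprint can capture from 0.8 m/yr of rain, while the
metabolic requirement is still comfortably met. Warming the same site
uniformly by 2 °C steepens the vapor-pressure gradient, pumps more
water per leaf, and lowers the ceiling:

```r
temperature_sensitivity(list(env), trait_set(), water_budget_params(),
                        allometry_config(), delta_t = 2,
                        mode = "both")$per_site
#> 34.7 m -> 29.6 m (-14.8%)
```

Holding everything else fixed, the stomatal density that maximizes the
ceiling at this site is 77.7 mm^-2 (raising `h_max` to 112.7 m) —
denser stomata would hit the water cap sooner, sparser ones would
under-use the available energy. Canopy albedo falls with height from
the bare-soil value toward the deep-canopy value as leaf area
accumulates:

```r
canopy_albedo(c(1, 10, 50), trait_set(), allometry_config())
#> [1] 0.279 0.209 0.155
```

All shipped parameter values are the package's own calibration for an
average tree (documented in `vignettes/treelim-methods.Rmd`); every law
is configurable through `allometry_config()` / YAML, and
`fit_scaling_law()` refits any of them from user data.

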