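# Shared fixtures: toy configurations, seeded random environments, and
# an independent energy-budget residual used as the solver oracle.

# Configuration in which every scaling relation is the identity, so all
# geometry can be followed by hand.
identity_config <- function(leaf_area_single = 1) {
  allometry_config(
    height_vs_diameter = scaling_law(1, 1, "cm", "m"),
    basal_flow_small = scaling_law(1, 1, "cm", "liters/day"),
    basal_flow_large = scaling_law(1, 1, "cm", "liters/day"),
    crossover_diameter = 1,
    canopy_radius = scaling_law(1, 1, "m", "m"),
    canopy_depth = scaling_law(1, 1, "m", "m"),
    root_radius = scaling_law(1, 1, "m", "m"),
    leaf_count = scaling_law(1, 1, "cm", "count"),
    leaf_area_single = leaf_area_single
  )
}

# Seeded random site climatologies spanning the generator's envelope.
random_envs <- function(n, seed) {
  generate_environments(environment_grid_spec(
    n_sites = n, correlation_mode = "independent", seed = seed,
    precipitation_range = c(0.1, 3), temperature_range = c(-5, 35),
    rh_range = c(0.15, 1), wind_range = c(0.5, 8),
    solar_range = c(80, 400)
  ))
}

# Cool-wet to hot-dry transect that stays in the water-limited regime;
# the setting in which the trait-optimum temperature trends are a clean
# monotone prediction of the model.
water_limited_transect <- function(n_sites = 8) {
  generate_environments(environment_grid_spec(
    n_sites = n_sites, precipitation_range = c(0.3, 0.9),
    temperature_range = c(8, 28), rh_range = c(0.25, 0.55),
    solar_range = c(230, 330), wind_range = c(3, 3)
  ))
}

# Energy-budget residual written out from first principles,
# independently of the package's solver internals: absorbed radiation
# minus (thermal emission + sensible + latent) at canopy temperature
# t_l, for one geometry row.
oracle_residual <- function(t_l, geom, env, traits) {
  sigma <- 5.670374419e-8
  cp <- 29.3
  lambda <- 44000
  es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  cc <- traits$effective_area_coefficients
  a_l <- cc[["c_L"]] * geom$total_leaf_area
  a_h <- cc[["c_H"]] * geom$total_leaf_area
  a_e <- cc[["c_E"]] * geom$total_leaf_area
  g_s <- traits$reference_stomatal_conductance * traits$stomatal_density /
    traits$reference_stomatal_density
  g_va <- 1.4 * 0.147 * sqrt(env$wind_speed / traits$leaf_characteristic_dimension)
  g_v <- if (g_s + g_va > 0) g_s * g_va / (g_s + g_va) else 0
  g_ha <- 1.4 * 0.135 * sqrt(env$wind_speed / traits$leaf_characteristic_dimension)
  absorbed <- env$solar_radiation * traits$leaf_shortwave_absorptivity *
    (1 - exp(-traits$canopy_extinction_coefficient * geom$leaf_area_index)) *
    geom$projected_canopy_area +
    traits$thermal_emissivity * sigma * (env$air_temperature + 273.15)^4 * a_l
  e_air <- env$relative_humidity * es(env$air_temperature)
  absorbed -
    (a_l * traits$thermal_emissivity * sigma * (t_l + 273.15)^4 +
       a_h * cp * g_ha * (t_l - env$air_temperature) +
       a_e * lambda * g_v * (es(t_l) - e_air) / env$air_pressure)
}
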