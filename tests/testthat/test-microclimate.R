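test_that("saturation vapor pressure follows the Tetens curve", {
  expect_equal(saturation_vapor_pressure(0), 0.6108, tolerance = 1e-9)
  expect_equal(saturation_vapor_pressure(20), 2.338, tolerance = 1e-3)
  t <- seq(-40, 59, by = 1)
  expect_true(all(saturation_vapor_pressure(t + 1) >
                    saturation_vapor_pressure(t)))
  expect_error(saturation_vapor_pressure(75), "within")
})

test_that("conductances combine stomatal and boundary-layer pathways", {
  env <- met_environment(1, 20, 0.5, 1, 200)
  traits <- trait_set(leaf_characteristic_dimension = 0.1)
  g <- conductances(traits, env)
  expect_equal(g$g_va, 1.4 * 0.147 * sqrt(10), tolerance = 1e-12)
  expect_equal(g$g_va, 0.651, tolerance = 1e-3)
  expect_equal(g$g_Ha, 1.4 * 0.135 * sqrt(10), tolerance = 1e-12)

  # g_s == g_va gives the symmetric series value g_s / 2
  sym <- trait_set(leaf_characteristic_dimension = 0.1,
                   reference_stomatal_conductance = g$g_va,
                   reference_stomatal_density = 200,
                   stomatal_density = 200)
  expect_equal(conductances(sym, env)$g_v, g$g_va / 2, tolerance = 1e-12)

  # closed stomata shut down the vapor pathway and evaporation
  closed <- trait_set(stomatal_density = 0)
  expect_equal(conductances(closed, env)$g_s, 0)
  expect_equal(conductances(closed, env)$g_v, 0)
  geom <- geometry_from_height(10, allometry_config())
  sunny <- met_environment(1, 20, 0.5, 3, 300)
  expect_equal(evaporative_flow(geom, sunny, closed), 0, tolerance = 1e-12)
})

test_that("absorbed radiation saturates to the deep-canopy limit", {
  cfg <- allometry_config()
  traits <- trait_set()
  env <- met_environment(1, 15, 0.6, 3, 1000)
  dark <- met_environment(1, 15, 0.6, 3, 0)

  geom <- geometry_from_height(100, cfg)  # k * LAI >= 5: optically deep
  expect_gte(traits$canopy_extinction_coefficient * geom$leaf_area_index, 5)
  shortwave <- absorbed_radiation(geom, env, traits) -
    absorbed_radiation(geom, dark, traits)
  limit <- traits$leaf_shortwave_absorptivity * env$solar_radiation *
    geom$projected_canopy_area
  expect_equal(shortwave, limit, tolerance = 0.01)

  # with no sun, what remains is ambient thermal over the thermal area
  sigma <- 5.670374419e-8
  a_l <- traits$effective_area_coefficients[["c_L"]] * geom$total_leaf_area
  expect_equal(absorbed_radiation(geom, dark, traits),
               traits$thermal_emissivity * sigma * (15 + 273.15)^4 * a_l,
               tolerance = 1e-12)
})

test_that("canopy albedo interpolates between soil and deep-canopy reflectances", {
  traits <- trait_set(soil_reflectance = 0.30, deep_canopy_reflectance = 0.15,
                      canopy_extinction_coefficient = 0.5)
  # identity config with leaf_area_single = 2*pi puts LAI(1 m) = 2
  cfg <- identity_config(leaf_area_single = 2 * pi)
  expect_equal(canopy_albedo(1, traits, cfg), 0.15 + 0.15 * exp(-1),
               tolerance = 1e-12)

  dflt <- allometry_config()
  expect_equal(canopy_albedo(1e-3, traits, dflt), 0.30, tolerance = 1e-3)
  expect_equal(canopy_albedo(150, traits, dflt), 0.15, tolerance = 1e-3)
  h <- seq(0.5, 150, length.out = 200)
  alb <- canopy_albedo(h, traits, dflt)
  expect_true(all(diff(alb) < 0))
  expect_true(all(alb <= 0.30 & alb >= 0.15))
})

test_that("a dark saturated atmosphere leaves the canopy at air temperature", {
  cfg <- allometry_config()
  traits <- trait_set(thermal_emissivity = 1)
  for (t_air in c(-5, 10, 25)) {
    env <- met_environment(1, t_air, 1, 2, 0)
    geom <- geometry_from_height(20, cfg)
    eb <- solve_energy_balance(geom, env, traits)
    expect_equal(eb$canopy_temperature, t_air, tolerance = 1e-6)
    expect_identical(eb$evaporative_molar_flux, 0)
    expect_identical(evaporative_flow(geom, env, traits), 0)
    # thermal emission equals sigma T^4 over the thermal effective area
    sigma <- 5.670374419e-8
    expect_equal(eb$emitted_thermal,
                 sigma * (t_air + 273.15)^4 * 2 * geom$total_leaf_area,
                 tolerance = 1e-9)
  }
})

test_that("energy balance closes and canopy runs warm when no vapor gradient exists", {
  envs <- random_envs(40, seed = 101)
  cfg <- allometry_config()
  traits <- trait_set()
  set.seed(202)
  heights <- exp(runif(40, log(0.5), log(120)))
  for (i in seq_along(envs)) {
    geom <- geometry_from_height(heights[i], cfg)
    eb <- solve_energy_balance(geom, envs[[i]], traits)
    expect_lt(abs(eb$residual), 1e-6 * max(1, eb$absorbed_radiation))
    expect_equal(eb$absorbed_radiation,
                 eb$emitted_thermal + eb$sensible_heat + eb$latent_heat,
                 tolerance = 1e-6)
  }
  # positive net radiation at RH = 1: no evaporative cooling below air temp
  humid <- met_environment(1, 18, 1, 3, 300)
  geom <- geometry_from_height(25, cfg)
  eb <- solve_energy_balance(geom, humid, traits)
  expect_gt(eb$canopy_temperature, 18)
})

test_that("Newton canopy temperature matches a fine grid search of the residual", {
  envs <- random_envs(10, seed = 31)
  cfg <- allometry_config()
  traits <- trait_set()
  set.seed(32)
  heights <- exp(runif(10, log(1), log(100)))
  for (i in seq_along(envs)) {
    geom <- geometry_from_height(heights[i], cfg)
    eb <- solve_energy_balance(geom, envs[[i]], traits)
    t_grid <- seq(envs[[i]]$air_temperature - 40,
                  envs[[i]]$air_temperature + 40, by = 0.001)
    res <- oracle_residual(t_grid, geom, envs[[i]], traits)
    t_oracle <- t_grid[which.min(abs(res))]
    expect_lt(abs(eb$canopy_temperature - t_oracle), 0.01)
  }
})

test_that("evaporative flow responds to humidity and sunlight in the right direction", {
  cfg <- allometry_config()
  traits <- trait_set()
  geom <- geometry_from_height(30, cfg)
  rh <- seq(0.2, 1, by = 0.1)
  qe_rh <- vapply(rh, function(r) {
    evaporative_flow(geom, met_environment(1, 20, r, 3, 250), traits)
  }, numeric(1))
  expect_true(all(diff(qe_rh) < 0))
  s <- seq(0, 400, by = 50)
  qe_s <- vapply(s, function(sw) {
    evaporative_flow(geom, met_environment(1, 20, 0.5, 3, sw), traits)
  }, numeric(1))
  expect_true(all(diff(qe_s) > 0))
})

test_that("molar flux converts to liters per day through water's molar volume", {
  cfg <- allometry_config()
  traits <- trait_set()
  env <- met_environment(1, 22, 0.45, 3, 280)
  geom <- geometry_from_height(35, cfg)
  eb <- solve_energy_balance(geom, env, traits)
  a_e <- traits$effective_area_coefficients[["c_E"]] * geom$total_leaf_area
  # 1e-3 mol m^-2 s^-1 over 1 m^2 is 1.5565 L/day; scale linearly
  expect_equal(evaporative_flow(geom, env, traits),
               eb$evaporative_molar_flux * a_e / 1e-3 * 1.556496,
               tolerance = 1e-6)
})
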