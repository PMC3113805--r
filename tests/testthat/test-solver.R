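test_that("flow curves combine the three components consistently", {
  cfg <- identity_config()
  cfg$basal_flow_small <- scaling_law(0.1, 2, "cm", "liters/day")
  cfg$basal_flow_large <- scaling_law(0.1, 2, "cm", "liters/day")
  env <- met_environment(1, 15, 0.6, 3, 250)
  traits <- trait_set()
  wp <- water_budget_params(0.5)
  h <- c(2, 5, 10)
  fc <- flow_curves(env, traits, wp, cfg, h)
  # Q0 = 0.1 h^2 (identity height-diameter law)
  expect_equal(fc$q_required, 0.1 * h^2, tolerance = 1e-12)
  # Qp = eff * P * pi * h^2, m^3/yr -> L/day
  expect_equal(fc$q_available, 0.5 * 1 * pi * h^2 * 1000 / 365.25,
               tolerance = 1e-12)
  expect_equal(fc$q_evaporative,
               evaporative_flow(geometry_from_height(h, cfg), env, traits),
               tolerance = 1e-12)
  # deterministic, bit for bit
  expect_identical(fc, flow_curves(env, traits, wp, cfg, h))
  # no rain, no supply
  dry <- met_environment(0, 15, 0.6, 3, 250)
  expect_true(all(flow_curves(dry, traits, wp, cfg, h)$q_available == 0))
  expect_error(flow_curves(env, traits, wp, cfg, c(3, 2, 1)), "increasing")
})

test_that("the solver recovers a closed-form crossing to 0.01 m", {
  res <- max_height_from_flows(function(h) 0.1 * h^3,
                               function(h) rep(100, length(h)),
                               mode = "metabolic_only")
  expect_equal(res$max_height, 10, tolerance = 0.01)
  expect_equal(res$binding_constraint, "metabolic")

  set.seed(5)
  for (i in 1:20) {
    eta <- runif(1, 2, 4)
    c_flow <- runif(1, 20, 500)
    h_true <- runif(1, 2, 120)
    b <- c_flow / h_true^eta
    res <- max_height_from_flows(function(h) b * h^eta,
                                 function(h) rep(c_flow, length(h)),
                                 mode = "metabolic_only")
    expect_lt(abs(res$max_height - h_true), 0.01)
  }
})

test_that("infeasibility, caps and detached islands are reported as data", {
  # requirement above supply everywhere: infeasible at the smallest height
  res <- max_height_from_flows(function(h) h + 100,
                               function(h) rep(1, length(h)),
                               mode = "metabolic_only")
  expect_true(is.na(res$max_height))
  expect_equal(res$binding_constraint, "infeasible")

  # supply above requirement everywhere: capped at the top of the domain
  res <- max_height_from_flows(function(h) rep(1, length(h)),
                               function(h) rep(2, length(h)),
                               mode = "metabolic_only")
  expect_equal(res$max_height, 150)
  expect_equal(res$binding_constraint, "cap")

  # a feasible island detached from the seedling region is diagnostic only
  qe <- function(h) pmax(0, 20 - h) + ifelse(h > 50 & h < 60, 30, 0)
  res <- max_height_from_flows(function(h) rep(10, length(h)), qe,
                               mode = "metabolic_only")
  expect_equal(res$max_height, 10, tolerance = 0.01)
  expect_equal(length(res$islands), 1L)
  expect_gt(res$islands[[1]][1], 45)

  # no rain in mode "both": water-bound at once
  env <- met_environment(0, 20, 0.5, 3, 300)
  full <- max_height(env, trait_set(), water_budget_params(),
                     allometry_config(), mode = "both")
  expect_true(is.na(full$max_height))
  expect_equal(full$binding_constraint, "infeasible")
})

test_that("every solve carries a feasibility certificate at its crossing", {
  cfg <- allometry_config()
  traits <- trait_set()
  wp <- water_budget_params()
  envs <- generate_environments(environment_grid_spec(n_sites = 6))
  for (env in envs) {
    res <- max_height(env, traits, wp, cfg, mode = "both")
    if (is.na(res$max_height) || res$binding_constraint == "cap") next
    h <- res$max_height
    fc_lo <- flow_curves(env, traits, wp, cfg, h - 0.02)
    fc_hi <- flow_curves(env, traits, wp, cfg, h + 0.02)
    expect_true(fc_lo$q_required <= fc_lo$q_evaporative &
                  fc_lo$q_evaporative <= fc_lo$q_available)
    expect_false(fc_hi$q_required <= fc_hi$q_evaporative &
                   fc_hi$q_evaporative <= fc_hi$q_available)
  }
})

test_that("bisection agrees with a 1 mm brute-force grid scan", {
  cfg <- allometry_config()
  traits <- trait_set()
  wp <- water_budget_params()
  envs <- random_envs(10, seed = 77)
  for (env in envs) {
    res <- max_height(env, traits, wp, cfg, mode = "both", tol = 0.001)
    if (is.na(res$max_height) || res$binding_constraint == "cap") next
    # brute force: first failure of the chain on a 1 mm grid
    grid <- seq(0.5, min(150, res$max_height + 5), by = 0.001)
    fc <- flow_curves(env, traits, wp, cfg, grid)
    ok <- fc$q_required <= fc$q_evaporative & fc$q_evaporative <= fc$q_available
    first_bad <- which(!ok)[1]
    expect_false(is.na(first_bad))
    h_oracle <- grid[first_bad - 1L]
    expect_lt(abs(res$max_height - h_oracle), 0.002)
  }
})

test_that("wet low-energy sites are metabolic-bound and arid sunny sites water-bound", {
  cfg <- allometry_config()
  traits <- trait_set()
  wp <- water_budget_params()
  wet_dim <- met_environment(2.5, 10, 0.85, 2, 120, site_id = "wet_cool")
  arid_sunny <- met_environment(0.3, 25, 0.25, 4, 330, site_id = "arid_hot")
  res_wet <- max_height(wet_dim, traits, wp, cfg, mode = "both")
  res_arid <- max_height(arid_sunny, traits, wp, cfg, mode = "both")
  expect_equal(res_wet$binding_constraint, "metabolic")
  expect_equal(res_arid$binding_constraint, "water")
  expect_gt(res_wet$max_height, res_arid$max_height)
})

test_that("height responds monotonically to the limiting resource", {
  cfg <- allometry_config()
  traits <- trait_set()
  wp <- water_budget_params()
  # water-limited: more rain, taller trees
  h_rain <- vapply(seq(0.3, 1.5, length.out = 6), function(p) {
    max_height(met_environment(p, 22, 0.35, 3, 300), traits, wp, cfg,
               mode = "both")$max_height
  }, numeric(1))
  expect_true(all(diff(h_rain) >= 0))
  # energy-limited: more sun, taller trees
  h_sun <- vapply(seq(100, 250, length.out = 6), function(s) {
    max_height(met_environment(2.5, 8, 0.85, 2, s), traits, wp, cfg,
               mode = "both")$max_height
  }, numeric(1))
  expect_true(all(diff(h_sun) >= 0))
})

test_that("temperature sensitivity is zero at zero shift and flips sign", {
  cfg <- allometry_config()
  traits <- trait_set()
  wp <- water_budget_params()
  envs <- water_limited_transect(5)
  zero <- temperature_sensitivity(envs, traits, wp, cfg, 0, mode = "both")
  expect_true(all(abs(zero$per_site$percent_change) < 1e-9))
  warm <- temperature_sensitivity(envs, traits, wp, cfg, 2, mode = "both")
  cool <- temperature_sensitivity(envs, traits, wp, cfg, -2, mode = "both")
  expect_lt(warm$mean_percent_change, 0)
  expect_gt(cool$mean_percent_change, 0)
  # deterministic per-site output
  warm2 <- temperature_sensitivity(envs, traits, wp, cfg, 2, mode = "both")
  expect_identical(warm$per_site, warm2$per_site)
  # a site infeasible before the shift is excluded and flagged
  with_dead <- c(envs, list(met_environment(0, 30, 0.2, 3, 350,
                                            site_id = "no_rain")))
  res <- temperature_sensitivity(with_dead, traits, wp, cfg, 2, mode = "both")
  expect_false(res$per_site$feasible_before[6])
  expect_equal(res$mean_percent_change, warm$mean_percent_change)
})

test_that("exponent perturbations shift predictions monotonically", {
  cfg <- allometry_config()
  traits <- trait_set()
  wp <- water_budget_params()
  envs <- water_limited_transect(4)
  perts <- c(-4, -2, 0, 2, 4)
  tab <- exponent_sensitivity(envs, traits, wp, cfg, "root_radius", perts,
                              mode = "both")
  expect_equal(nrow(tab), length(perts))
  expect_equal(tab$median_height_change_pct[perts == 0], 0)
  mags <- abs(tab$median_height_change_pct)
  expect_true(all(diff(mags[perts <= 0]) <= 0))   # shrinking toward 0
  expect_true(all(diff(mags[perts >= 0]) >= 0))   # growing away from 0
  expect_error(
    exponent_sensitivity(envs, traits, wp, cfg, "no_such_law", perts),
    "unknown law"
  )
  # with observations the summary becomes a median signed relative error
  obs <- rep(20, 4)
  tab_obs <- exponent_sensitivity(envs, traits, wp, cfg, "root_radius", 0,
                                  observed = obs, mode = "both")
  expect_true("median_relative_error" %in% names(tab_obs))
})

test_that("relative error is signed and guarded", {
  expect_equal(relative_error(20, 20), 0)
  expect_equal(relative_error(40, 20), 1)
  expect_equal(relative_error(15, 20), -0.25)
  expect_error(relative_error(10, 0), "positive")
})
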