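# Canopy microclimate: the energy budget that converts absorbed
# radiation into emitted thermal, sensible, and latent losses, solved
# for canopy temperature; its conversion to an evaporative flow rate;
# and the height-dependent canopy albedo.
#
# Notation guard: capital R_abs is absorbed radiation (W); lower-case r
# is reserved for radii (m).

#' Environment-independent physiological traits
#'
#' The single set of tree traits applied across all environments.
#' Stomatal conductance scales linearly with stomatal density through
#' the reference pair; boundary-layer conductances follow the standard
#' wind/leaf-size forms (see [conductances()]). Densities are the
#' average over both sides of the leaf.
#'
#' @param stomatal_density Stomata per mm^2 of leaf, leaf-side average.
#' @param leaf_characteristic_dimension Characteristic leaf size, m.
#' @param reference_stomatal_conductance Stomatal conductance to water
#'   vapor, mol m^-2 s^-1, at `reference_stomatal_density`; an
#'   annual-mean effective value, not an instantaneous maximum.
#' @param reference_stomatal_density Density (stomata/mm^2) at which the
#'   reference conductance applies.
#' @param leaf_shortwave_absorptivity Fraction of intercepted shortwave
#'   a leaf absorbs.
#' @param canopy_extinction_coefficient Beer-Lambert extinction
#'   coefficient of the canopy (per unit LAI).
#' @param thermal_emissivity Canopy thermal emissivity (= longwave
#'   absorptivity), fraction.
#' @param soil_reflectance Shortwave reflectance of bare ground,
#'   fraction.
#' @param deep_canopy_reflectance Shortwave reflectance of an optically
#'   deep canopy, fraction.
#' @param effective_area_coefficients Named triple `(c_L, c_H, c_E)`
#'   multiplying the total one-sided leaf area to give the effective
#'   areas for thermal radiation, sensible heat, and evaporation.
#'   Defaults: 2 (two-sided emission), 2, 1 (hypostomatous).
#'
#' @return An object of class `trait_set`.
#' @export
#' @examples
#' trait_set(stomatal_density = 150)
trait_set <- function(stomatal_density = 200,
                      leaf_characteristic_dimension = 0.05,
                      reference_stomatal_conductance = 0.045,
                      reference_stomatal_density = 200,
                      leaf_shortwave_absorptivity = 0.8,
                      canopy_extinction_coefficient = 0.5,
                      thermal_emissivity = 0.97,
                      soil_reflectance = 0.30,
                      deep_canopy_reflectance = 0.15,
                      effective_area_coefficients = c(c_L = 2, c_H = 2, c_E = 1)) {
  fractions <- list(leaf_shortwave_absorptivity = leaf_shortwave_absorptivity,
                    thermal_emissivity = thermal_emissivity,
                    soil_reflectance = soil_reflectance,
                    deep_canopy_reflectance = deep_canopy_reflectance)
  for (nm in names(fractions)) {
    v <- fractions[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("trait_set: '", nm, "' must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  nonneg <- list(stomatal_density = stomatal_density,
                 leaf_characteristic_dimension = leaf_characteristic_dimension,
                 reference_stomatal_conductance = reference_stomatal_conductance,
                 reference_stomatal_density = reference_stomatal_density,
                 canopy_extinction_coefficient = canopy_extinction_coefficient)
  for (nm in names(nonneg)) {
    v <- nonneg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("trait_set: '", nm, "' must be a non-negative number", call. = FALSE)
    }
  }
  if (length(effective_area_coefficients) != 3L ||
      any(!is.finite(effective_area_coefficients)) ||
      any(effective_area_coefficients < 0)) {
    stop("trait_set: effective_area_coefficients must be 3 non-negative numbers",
         call. = FALSE)
  }
  names(effective_area_coefficients) <- c("c_L", "c_H", "c_E")
  structure(c(nonneg, fractions,
              list(effective_area_coefficients = effective_area_coefficients)),
            class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat("<trait_set>\n")
  cat(sprintf("  stomatal density      %g mm^-2 (g_s = %g mol m^-2 s^-1 at %g mm^-2)\n",
              x$stomatal_density, x$reference_stomatal_conductance,
              x$reference_stomatal_density))
  cat(sprintf("  leaf dimension        %g m\n", x$leaf_characteristic_dimension))
  cat(sprintf("  shortwave absorptivity %g, extinction k = %g, emissivity %g\n",
              x$leaf_shortwave_absorptivity, x$canopy_extinction_coefficient,
              x$thermal_emissivity))
  cat(sprintf("  reflectances          soil %g, deep canopy %g\n",
              x$soil_reflectance, x$deep_canopy_reflectance))
  cat(sprintf("  effective areas       c_L = %g, c_H = %g, c_E = %g (x leaf area)\n",
              x$effective_area_coefficients[1], x$effective_area_coefficients[2],
              x$effective_area_coefficients[3]))
  invisible(x)
}

# Tetens form without the domain guard, for internal solver use.
tetens <- function(t_c) 0.6108 * exp(17.27 * t_c / (t_c + 237.3))

# d e_s / dT, kPa per K
tetens_slope <- function(t_c) {
  tetens(t_c) * 17.27 * 237.3 / (t_c + 237.3)^2
}

#' Saturation vapor pressure of water
#'
#' Tetens form `0.6108 * exp(17.27 T / (T + 237.3))` (kPa, T in
#' degrees C); strictly increasing on the valid range.
#'
#' @param t_c Temperature(s), degrees C, in \[-40, 60\].
#'
#' @return Saturation vapor pressure, kPa.
#' @export
#' @examples
#' saturation_vapor_pressure(c(0, 20))
saturation_vapor_pressure <- function(t_c) {
  if (!is.numeric(t_c) || any(!is.finite(t_c)) ||
      any(t_c < -40) || any(t_c > 60)) {
    stop("saturation_vapor_pressure: temperature must be within [-40, 60] C",
         call. = FALSE)
  }
  tetens(t_c)
}

#' Leaf conductances to heat and water vapor
#'
#' Stomatal conductance is linear in stomatal density through the
#' reference pair; leaf boundary-layer conductances follow the standard
#' forced-convection forms `1.4 * 0.147 * sqrt(u / d)` (vapor) and
#' `1.4 * 0.135 * sqrt(u / d)` (heat). The total vapor conductance is
#' the series combination of stomatal and boundary-layer conductances.
#'
#' @param traits A [trait_set()].
#' @param env A [met_environment()].
#'
#' @return A list with components `g_s`, `g_va`, `g_v`, `g_Ha`, all in
#'   mol m^-2 s^-1.
#' @export
#' @examples
#' conductances(trait_set(), met_environment(1, 15, 0.6, 1, 200))
conductances <- function(traits, env) {
  stopifnot(inherits(traits, "trait_set"), inherits(env, "met_environment"))
  d <- traits$leaf_characteristic_dimension
  if (d <= 0) {
    stop("conductances: leaf_characteristic_dimension must be > 0",
         call. = FALSE)
  }
  if (traits$reference_stomatal_density <= 0) {
    stop("conductances: reference_stomatal_density must be > 0", call. = FALSE)
  }
  g_s <- traits$reference_stomatal_conductance *
    traits$stomatal_density / traits$reference_stomatal_density
  g_va <- 1.4 * 0.147 * sqrt(env$wind_speed / d)
  g_Ha <- 1.4 * 0.135 * sqrt(env$wind_speed / d)
  g_v <- if (g_s + g_va > 0) g_s * g_va / (g_s + g_va) else 0
  list(g_s = g_s, g_va = g_va, g_v = g_v, g_Ha = g_Ha)
}

# Effective areas (m^2) for thermal, sensible and latent exchange:
# linear in the total one-sided leaf area.
effective_areas <- function(geom, traits) {
  cc <- traits$effective_area_coefficients
  list(a_thermal = cc[["c_L"]] * geom$total_leaf_area,
       a_sensible = cc[["c_H"]] * geom$total_leaf_area,
       a_evaporative = cc[["c_E"]] * geom$total_leaf_area)
}

#' Radiation absorbed by the canopy
#'
#' Shortwave: incoming radiation times the canopy absorption
#' coefficient `absorptivity * (1 - exp(-k * LAI))` over the projected
#' canopy area (Beer-Lambert closure; for a deep canopy this tends to
#' `absorptivity * S * A_proj`). Longwave: ambient thermal emission at
#' air temperature absorbed over the thermal effective area, so a
#' canopy in a dark, saturated atmosphere is in equilibrium at air
#' temperature.
#'
#' @param geom A [geometry_from_height()] result (any number of rows).
#' @param env A [met_environment()].
#' @param traits A [trait_set()].
#' @param constants See [energy_constants()].
#'
#' @return Absorbed radiation per tree, W (vector over geometry rows).
#' @export
absorbed_radiation <- function(geom, env, traits,
                               constants = energy_constants()) {
  stopifnot(inherits(geom, "tree_geometry"), inherits(env, "met_environment"),
            inherits(traits, "trait_set"))
  k <- traits$canopy_extinction_coefficient
  alpha_canopy <- traits$leaf_shortwave_absorptivity *
    (1 - exp(-k * geom$leaf_area_index))
  shortwave <- env$solar_radiation * alpha_canopy * geom$projected_canopy_area
  areas <- effective_areas(geom, traits)
  t_air_k <- celsius_to_kelvin(env$air_temperature)
  longwave <- traits$thermal_emissivity * constants$stefan_boltzmann *
    t_air_k^4 * areas$a_thermal
  shortwave + longwave
}

#' Canopy albedo as a function of tree height
#'
#' The canopy-soil system reflects like bare ground when the canopy is
#' sparse and like an optically deep canopy when it is dense:
#' `albedo = rho_deep + (rho_soil - rho_deep) * exp(-k * LAI(h))`.
#' Since LAI grows with height, albedo moves monotonically from the
#' soil value toward the deep-canopy value as trees get taller.
#'
#' @param h Height(s), m, positive.
#' @param traits A [trait_set()] (supplies the two reflectances and k).
#' @param cfg An [allometry_config()] (supplies LAI(h)).
#'
#' @return Albedo fraction(s), bounded by the two reflectances.
#' @export
#' @examples
#' canopy_albedo(c(1, 10, 50), trait_set(), allometry_config())
canopy_albedo <- function(h, traits, cfg) {
  stopifnot(inherits(traits, "trait_set"), inherits(cfg, "allometry_config"))
  geom <- geometry_from_height(h, cfg)
  traits$deep_canopy_reflectance +
    (traits$soil_reflectance - traits$deep_canopy_reflectance) *
    exp(-traits$canopy_extinction_coefficient * geom$leaf_area_index)
}

# Vectorized safeguarded Newton for the canopy temperature. The loss
# side is strictly increasing in T_L, so the root is unique; a sign
# change over [t_air - 40, t_air + 40] is asserted before refining and
# every Newton step is kept inside the shrinking bracket (bisection
# fallback). Returns canopy temperature(s) in degrees C.
solve_canopy_temperature <- function(r_abs, a_thermal, a_sensible,
                                     a_evaporative, t_air, e_air, pressure,
                                     g_v, g_Ha, emissivity,
                                     constants = energy_constants(),
                                     max_iter = 100L) {
  n <- length(r_abs)
  sigma <- constants$stefan_boltzmann
  cp <- constants$cp_molar
  lambda <- constants$latent_heat_vaporization

  loss <- function(t_l) {
    a_thermal * emissivity * sigma * celsius_to_kelvin(t_l)^4 +
      a_sensible * cp * g_Ha * (t_l - t_air) +
      a_evaporative * lambda * g_v * (tetens(t_l) - e_air) / pressure
  }
  dloss <- function(t_l) {
    4 * a_thermal * emissivity * sigma * celsius_to_kelvin(t_l)^3 +
      a_sensible * cp * g_Ha +
      a_evaporative * lambda * g_v * tetens_slope(t_l) / pressure
  }

  lo <- rep_len(t_air - 40, n)
  hi <- rep_len(t_air + 40, n)
  f_lo <- loss(lo) - r_abs
  f_hi <- loss(hi) - r_abs
  if (any(f_lo > 0) || any(f_hi < 0)) {
    stop("solve_canopy_temperature: no sign change in [t_air - 40, t_air + 40];",
         " energy budget has no canopy-temperature root in range", call. = FALSE)
  }

  t_l <- rep_len(t_air + 0, n)
  f <- loss(t_l) - r_abs
  tol <- 1e-9 * pmax(1, r_abs)
  for (iter in seq_len(max_iter)) {
    active <- abs(f) > tol
    if (!any(active)) break
    # shrink the bracket with the current sign
    lo <- ifelse(f < 0, t_l, lo)
    hi <- ifelse(f > 0, t_l, hi)
    step <- f / dloss(t_l)
    cand <- t_l - step
    bad <- !is.finite(cand) | cand <= lo | cand >= hi
    cand <- ifelse(bad, (lo + hi) / 2, cand)
    t_l <- ifelse(active, cand, t_l)
    f <- loss(t_l) - r_abs
  }
  if (any(abs(f) > 1e-6 * pmax(1, r_abs))) {
    stop(sprintf(
      "solve_canopy_temperature: not converged after %d iterations (max |residual| %.3g W)",
      max_iter, max(abs(f))), call. = FALSE)
  }
  t_l
}

#' Solve the canopy energy budget
#'
#' Finds the canopy temperature at which absorbed radiation balances
#' the sum of emitted thermal radiation, sensible heat loss, and latent
#' heat loss:
#' `R_abs = A_L e sigma T_L^4 + A_H c_p g_Ha (T_L - T_air)
#'  + A_E lambda g_v (e_s(T_L) - e_a) / p_a`,
#' with each effective area `A_X` proportional to the total one-sided
#' leaf area and `e_a = RH * e_s(T_air)`. The loss side is strictly
#' increasing in canopy temperature, so the balance point is unique.
#'
#' @inheritParams absorbed_radiation
#'
#' @return A data frame of class `energy_balance_result`, one row per
#'   geometry row, with columns `canopy_temperature` (degrees C),
#'   `absorbed_radiation`, `emitted_thermal`, `sensible_heat`,
#'   `latent_heat` (W), `evaporative_molar_flux` (mol m^-2 s^-1), and
#'   `residual` (W).
#' @export
#' @examples
#' geom <- geometry_from_height(30, allometry_config())
#' env <- met_environment(1, 15, 0.6, 3, 250)
#' solve_energy_balance(geom, env, trait_set())
solve_energy_balance <- function(geom, env, traits,
                                 constants = energy_constants()) {
  stopifnot(inherits(geom, "tree_geometry"), inherits(env, "met_environment"),
            inherits(traits, "trait_set"))
  g <- conductances(traits, env)
  areas <- effective_areas(geom, traits)
  r_abs <- absorbed_radiation(geom, env, traits, constants)
  e_air <- env$relative_humidity * tetens(env$air_temperature)

  t_l <- solve_canopy_temperature(
    r_abs, areas$a_thermal, areas$a_sensible, areas$a_evaporative,
    env$air_temperature, e_air, env$air_pressure, g$g_v, g$g_Ha,
    traits$thermal_emissivity, constants
  )

  emitted <- areas$a_thermal * traits$thermal_emissivity *
    constants$stefan_boltzmann * celsius_to_kelvin(t_l)^4
  sensible <- areas$a_sensible * constants$cp_molar * g$g_Ha *
    (t_l - env$air_temperature)
  e_flux <- g$g_v * (tetens(t_l) - e_air) / env$air_pressure
  latent <- areas$a_evaporative * constants$latent_heat_vaporization * e_flux
  out <- data.frame(
    canopy_temperature = t_l,
    absorbed_radiation = r_abs,
    emitted_thermal = emitted,
    sensible_heat = sensible,
    latent_heat = latent,
    evaporative_molar_flux = e_flux,
    residual = r_abs - (emitted + sensible + latent)
  )
  class(out) <- c("energy_balance_result", "data.frame")
  out
}

#' Evaporative flow rate through the tree
#'
#' Trees act as passive solar pumps: the internal flow equals the water
#' evaporated from the canopy. The molar evaporative flux from the
#' energy budget, over the evaporative effective area, is converted to
#' liquid volume via the molar mass and density of water.
#'
#' @inheritParams absorbed_radiation
#'
#' @return Evaporative flow(s), liters/day (vector over geometry rows).
#' @export
#' @examples
#' geom <- geometry_from_height(30, allometry_config())
#' evaporative_flow(geom, met_environment(1, 15, 0.6, 3, 250), trait_set())
evaporative_flow <- function(geom, env, traits,
                             constants = energy_constants()) {
  balance <- solve_energy_balance(geom, env, traits, constants)
  areas <- effective_areas(geom, traits)
  molar_flux_to_liters_per_day(balance$evaporative_molar_flux,
                               areas$a_evaporative, constants)
}
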