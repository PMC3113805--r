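# Physical constants and the unit-conversion contract.
#
# Module boundaries use: heights and radii in m, trunk diameters in cm,
# flows in liters/day, fluxes in W or W m^-2, vapor pressures in kPa,
# conductances in mol m^-2 s^-1. A year is 365.25 days. Every conversion
# between these lives in this file.

#' Physical constants of the canopy energy budget
#'
#' Returns the constants used by [solve_energy_balance()] and
#' [evaporative_flow()]. All are standard leaf-microclimate values;
#' override individual entries to explore their effect.
#'
#' @param stefan_boltzmann Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param cp_molar Molar heat capacity of air, J mol^-1 K^-1.
#' @param latent_heat_vaporization Latent heat of vaporization of water,
#'   J mol^-1, treated as temperature-independent.
#' @param molar_mass_water Molar mass of water, kg mol^-1.
#' @param density_water Density of liquid water, kg m^-3.
#'
#' @return A named list of constants.
#' @export
#' @examples
#' energy_constants()$latent_heat_vaporization
energy_constants <- function(stefan_boltzmann = 5.670374419e-8,
                             cp_molar = 29.3,
                             latent_heat_vaporization = 44000,
                             molar_mass_water = 0.018015,
                             density_water = 1000) {
  list(
    stefan_boltzmann = stefan_boltzmann,
    cp_molar = cp_molar,
    latent_heat_vaporization = latent_heat_vaporization,
    molar_mass_water = molar_mass_water,
    density_water = density_water
  )
}

DAYS_PER_YEAR <- 365.25
SECONDS_PER_DAY <- 86400
LITERS_PER_M3 <- 1000
KELVIN_OFFSET <- 273.15

# m^3 yr^-1 -> liters day^-1
m3_per_year_to_liters_per_day <- function(x) {
  x * LITERS_PER_M3 / DAYS_PER_YEAR
}

# molar evaporative flux (mol m^-2 s^-1) over an effective area (m^2)
# -> liters day^-1 of liquid water
molar_flux_to_liters_per_day <- function(flux_mol_m2_s, area_m2,
                                         constants = energy_constants()) {
  volume_m3_s <- flux_mol_m2_s * area_m2 * constants$molar_mass_water /
    constants$density_water
  volume_m3_s * SECONDS_PER_DAY * LITERS_PER_M3
}

celsius_to_kelvin <- function(t_c) t_c + KELVIN_OFFSET
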