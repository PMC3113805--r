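# Available flow from precipitation captured over the root footprint.
# Direct interception only: runoff, pooling and subsurface storage are
# outside the model.

#' Water-budget parameters
#'
#' @param root_absorption_efficiency Fraction of the precipitation
#'   falling over the root footprint that the roots absorb, in [0, 1].
#'   A single calibratable scalar per run.
#'
#' @return An object of class `water_budget_params`.
#' @export
water_budget_params <- function(root_absorption_efficiency = 0.4) {
  if (!is.numeric(root_absorption_efficiency) ||
      length(root_absorption_efficiency) != 1L ||
      !is.finite(root_absorption_efficiency) ||
      root_absorption_efficiency < 0 || root_absorption_efficiency > 1) {
    stop("water_budget_params: root_absorption_efficiency must be in [0, 1]",
         call. = FALSE)
  }
  structure(list(root_absorption_efficiency =
                   as.numeric(root_absorption_efficiency)),
            class = "water_budget_params")
}

#' Available flow rate from precipitation
#'
#' The water available to a tree of height `h`: the precipitation
#' falling on the flat ground directly above its root system, times the
#' root absorption efficiency. The root footprint is a disc whose
#' radius follows the configured root-extent scaling law.
#'
#' @param h Height(s), m, positive.
#' @param precipitation Precipitation rate, m/yr (>= 0).
#' @param params A [water_budget_params()].
#' @param cfg An [allometry_config()].
#'
#' @return Available flow(s), liters/day. Linear in precipitation and
#'   in efficiency; scales with height as the root-radius law squared.
#' @export
#' @examples
#' available_flow(30, 1.0, water_budget_params(0.5), allometry_config())
available_flow <- function(h, precipitation, params, cfg) {
  stopifnot(inherits(params, "water_budget_params"),
            inherits(cfg, "allometry_config"))
  if (!is.numeric(precipitation) || any(!is.finite(precipitation)) ||
      any(precipitation < 0)) {
    stop("available_flow: 'precipitation' must be >= 0", call. = FALSE)
  }
  r_root <- evaluate_law(cfg$root_radius, h)
  m3_per_year <- params$root_absorption_efficiency * precipitation *
    pi * r_root^2
  m3_per_year_to_liters_per_day(m3_per_year)
}
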