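# Maximum-height solver: combine the required (Q0), evaporative
# (Qevap), and available (Qp) flow curves and find the largest height at
# which Q0 <= Qevap <= Qp still holds, plus the temperature-shift and
# exponent-perturbation sensitivity analyses.

#' Flow curves of the limitation diagram
#'
#' Evaluates, on a height grid: the basal metabolic requirement Q0
#' (environment-independent), the precipitation-available supply Qp,
#' and the energy-driven evaporative flow Qevap. Their first crossing
#' sets the maximum sustainable height.
#'
#' @param env A [met_environment()].
#' @param traits A [trait_set()].
#' @param params A [water_budget_params()].
#' @param cfg An [allometry_config()].
#' @param h_grid Strictly increasing positive heights, m.
#' @param constants See [energy_constants()].
#'
#' @return A data frame of class `flow_curves` with columns `height`,
#'   `q_required`, `q_available`, `q_evaporative` (liters/day).
#' @export
#' @examples
#' env <- met_environment(1, 12, 0.6, 3, 230)
#' flow_curves(env, trait_set(), water_budget_params(), allometry_config(),
#'             h_grid = c(10, 30, 60))
flow_curves <- function(env, traits, params, cfg, h_grid,
                        constants = energy_constants()) {
  if (!is.numeric(h_grid) || any(h_grid <= 0) || any(diff(h_grid) <= 0)) {
    stop("flow_curves: 'h_grid' must be strictly increasing and positive",
         call. = FALSE)
  }
  geom <- geometry_from_height(h_grid, cfg)
  out <- data.frame(
    height = h_grid,
    q_required = basal_flow(geom$trunk_diameter, cfg),
    q_available = available_flow(h_grid, env$precipitation, params, cfg),
    q_evaporative = evaporative_flow(geom, env, traits, constants)
  )
  class(out) <- c("flow_curves", "data.frame")
  out
}

# Feasibility of the constraint chain Q0 <= Qevap (<= Qp in mode "both")
# at given heights, from flow functions of height.
chain_holds <- function(h, q_required_fun, q_evaporative_fun, q_available_fun,
                        mode) {
  q0 <- q_required_fun(h)
  qe <- q_evaporative_fun(h)
  ok <- qe >= q0
  if (mode == "both") ok <- ok & (q_available_fun(h) >= qe)
  ok
}

#' Maximum height from arbitrary flow functions
#'
#' The search engine behind [max_height()], exposed so custom or
#' simplified flow curves can be solved directly: scan a log-spaced
#' height grid, find the feasible region attached to the smallest
#' height (a tree must grow through every intermediate size), and
#' bisect its upper edge. Feasible stretches detached from the small-
#' tree region are reported as diagnostics, not used.
#'
#' @param q_required_fun,q_evaporative_fun,q_available_fun Vectorized
#'   functions of height (m) returning flows (liters/day).
#'   `q_available_fun` may be `NULL` in mode `"metabolic_only"`.
#' @param mode `"metabolic_only"` checks Qevap >= Q0 only (the
#'   recommended practical procedure once the root absorption
#'   efficiency is calibrated, since Qp scales nearly as Q0);
#'   `"both"` enforces the full chain Q0 <= Qevap <= Qp.
#' @param h_min,h_cap Search domain, m (default 0.5 to 150, seedling to
#'   the tallest known trees).
#' @param n_grid Number of log-spaced scan points.
#' @param tol Bisection tolerance on the crossing height, m.
#'
#' @return A list of class `max_height_result`: `max_height` (m, `NA`
#'   if infeasible at `h_min`), `binding_constraint` (`"metabolic"`,
#'   `"water"`, `"cap"`, or `"infeasible"`), `bracket`, `curves` (the
#'   scan as a `flow_curves`-shaped data frame), `islands` (detached
#'   feasible height intervals), and `mode`.
#' @export
#' @examples
#' # constant evaporative supply against a cubic requirement
#' res <- max_height_from_flows(function(h) 0.1 * h^3, function(h) rep(100, length(h)),
#'                              mode = "metabolic_only")
#' res$max_height # ~10
max_height_from_flows <- function(q_required_fun, q_evaporative_fun,
                                  q_available_fun = NULL,
                                  mode = c("metabolic_only", "both"),
                                  h_min = 0.5, h_cap = 150,
                                  n_grid = 400, tol = 0.01) {
  mode <- match.arg(mode)
  if (mode == "both" && is.null(q_available_fun)) {
    stop("max_height_from_flows: mode 'both' needs 'q_available_fun'",
         call. = FALSE)
  }
  grid <- exp(seq(log(h_min), log(h_cap), length.out = n_grid))
  q0 <- q_required_fun(grid)
  qe <- q_evaporative_fun(grid)
  qp <- if (is.null(q_available_fun)) rep(NA_real_, n_grid)
        else q_available_fun(grid)
  curves <- data.frame(height = grid, q_required = q0, q_available = qp,
                       q_evaporative = qe)
  class(curves) <- c("flow_curves", "data.frame")

  feasible <- qe >= q0
  if (mode == "both") feasible <- feasible & (qp >= qe)

  runs <- rle(feasible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  feas_runs <- which(runs$values)
  island_of <- function(i) c(grid[starts[i]], grid[ends[i]])

  if (!feasible[1]) {
    islands <- lapply(feas_runs, island_of)
    return(structure(list(max_height = NA_real_,
                          binding_constraint = "infeasible",
                          bracket = c(NA_real_, NA_real_),
                          curves = curves, islands = islands, mode = mode),
                     class = "max_height_result"))
  }
  # islands are the feasible runs beyond the one attached to h_min
  islands <- lapply(feas_runs[-1], island_of)

  i_end <- ends[1]  # last grid index of the attached feasible run
  if (i_end == n_grid) {
    return(structure(list(max_height = h_cap, binding_constraint = "cap",
                          bracket = c(h_cap, h_cap),
                          curves = curves, islands = islands, mode = mode),
                     class = "max_height_result"))
  }

  lo <- grid[i_end]
  hi <- grid[i_end + 1L]
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (chain_holds(mid, q_required_fun, q_evaporative_fun, q_available_fun,
                    mode)) lo <- mid else hi <- mid
  }
  h_star <- (lo + hi) / 2

  q0_hi <- q_required_fun(hi)
  qe_hi <- q_evaporative_fun(hi)
  binding <- "metabolic"
  if (mode == "both") {
    qp_hi <- q_available_fun(hi)
    viol_meta <- q0_hi - qe_hi
    viol_water <- qe_hi - qp_hi
    if (viol_water > viol_meta) binding <- "water"
  }
  structure(list(max_height = h_star, binding_constraint = binding,
                 bracket = c(lo, hi), curves = curves, islands = islands,
                 mode = mode),
            class = "max_height_result")
}

#' @export
print.max_height_result <- function(x, ...) {
  if (is.na(x$max_height)) {
    cat("<max_height_result> infeasible at the smallest search height\n")
  } else {
    cat(sprintf("<max_height_result> h_max = %.2f m (%s-bound, mode %s)\n",
                x$max_height, x$binding_constraint, x$mode))
  }
  if (length(x$islands)) {
    cat(sprintf("  note: %d detached feasible height interval(s) ignored\n",
                length(x$islands)))
  }
  invisible(x)
}

#' Maximum sustainable tree height in a given climate
#'
#' Builds the three flow curves for the site and finds the largest
#' height at which the constraint chain Q0 <= Qevap (<= Qp) holds,
#' i.e. the tallest tree that can use the site's energy to meet its
#' metabolic needs without exceeding its water supply.
#'
#' @inheritParams flow_curves
#' @inheritParams max_height_from_flows
#'
#' @return A `max_height_result`; see [max_height_from_flows()].
#'   Infeasibility at `h_min` is data (an arid site supporting no
#'   trees), not an error.
#' @export
#' @examples
#' env <- met_environment(1.5, 10, 0.7, 3, 210)
#' max_height(env, trait_set(), water_budget_params(), allometry_config())
max_height <- function(env, traits, params, cfg,
                       mode = c("metabolic_only", "both"),
                       h_min = 0.5, h_cap = 150, n_grid = 400, tol = 0.01,
                       constants = energy_constants()) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "met_environment"))
  q_required_fun <- function(h) basal_flow(diameter_from_height(h, cfg), cfg)
  q_evaporative_fun <- function(h) {
    evaporative_flow(geometry_from_height(h, cfg), env, traits, constants)
  }
  q_available_fun <- function(h) {
    available_flow(h, env$precipitation, params, cfg)
  }
  max_height_from_flows(q_required_fun, q_evaporative_fun, q_available_fun,
                        mode = mode, h_min = h_min, h_cap = h_cap,
                        n_grid = n_grid, tol = tol)
}

#' Response of predicted maximum heights to a uniform temperature shift
#'
#' Recomputes every site's maximum height with air temperature shifted
#' by `delta_t` (all traits and other meteorology fixed) and reports the
#' per-site and mean percent change. Sites infeasible before the shift
#' are excluded from the mean and flagged.
#'
#' @param envs A list of [met_environment()] objects.
#' @param traits,params,cfg,mode,constants Passed to [max_height()].
#' @param delta_t Temperature shift, degrees C.
#' @param ... Further arguments to [max_height()].
#'
#' @return A list with `per_site` (data frame: `site_id`, `h_before`,
#'   `h_after`, `percent_change`, `feasible_before`) and
#'   `mean_percent_change` over sites feasible before the shift.
#' @export
temperature_sensitivity <- function(envs, traits, params, cfg, delta_t,
                                    mode = c("metabolic_only", "both"),
                                    constants = energy_constants(), ...) {
  mode <- match.arg(mode)
  if (!length(envs)) stop("temperature_sensitivity: empty site list",
                          call. = FALSE)
  rows <- lapply(envs, function(env) {
    before <- max_height(env, traits, params, cfg, mode = mode,
                         constants = constants, ...)
    shifted <- env
    shifted$air_temperature <- env$air_temperature + delta_t
    after <- max_height(shifted, traits, params, cfg, mode = mode,
                        constants = constants, ...)
    feasible <- !is.na(before$max_height)
    data.frame(
      site_id = env$site_id,
      h_before = before$max_height,
      h_after = after$max_height,
      percent_change = if (feasible && !is.na(after$max_height)) {
        100 * (after$max_height - before$max_height) / before$max_height
      } else NA_real_,
      feasible_before = feasible
    )
  })
  per_site <- do.call(rbind, rows)
  list(per_site = per_site,
       mean_percent_change = mean(per_site$percent_change[
         per_site$feasible_before], na.rm = TRUE))
}

#' Sensitivity of predictions to a scaling exponent
#'
#' Perturbs one configured exponent by each given percentage,
#' recomputes the per-site maximum heights, and summarizes the shift:
#' the median percent height change versus the unperturbed run, or,
#' when observed heights are supplied, the median signed relative error
#' of the perturbed predictions.
#'
#' @param envs A list of [met_environment()] objects.
#' @param traits,params,cfg,mode,constants Passed to [max_height()].
#' @param law_name Name of a scaling law in `cfg` (e.g.
#'   `"root_radius"`).
#' @param perturbations Percent changes applied to the exponent.
#' @param observed Optional observed maximum heights (m), one per site.
#' @param ... Further arguments to [max_height()].
#'
#' @return A data frame with one row per perturbation: columns
#'   `perturbation_pct` and `median_height_change_pct` (or
#'   `median_relative_error` when `observed` is given).
#' @export
exponent_sensitivity <- function(envs, traits, params, cfg, law_name,
                                 perturbations, observed = NULL,
                                 mode = c("metabolic_only", "both"),
                                 constants = energy_constants(), ...) {
  mode <- match.arg(mode)
  if (!law_name %in% CONFIG_LAWS) {
    stop("exponent_sensitivity: unknown law '", law_name, "'; expected one of ",
         paste(CONFIG_LAWS, collapse = ", "), call. = FALSE)
  }
  if (!is.null(observed) && length(observed) != length(envs)) {
    stop("exponent_sensitivity: 'observed' must have one height per site",
         call. = FALSE)
  }
  heights_for <- function(cfg_i) {
    vapply(envs, function(env) {
      max_height(env, traits, params, cfg_i, mode = mode,
                 constants = constants, ...)$max_height
    }, numeric(1))
  }
  base_h <- heights_for(cfg)
  rows <- lapply(perturbations, function(pct) {
    cfg_i <- cfg
    law <- cfg_i[[law_name]]
    cfg_i[[law_name]] <- scaling_law(law$prefactor,
                                     law$exponent * (1 + pct / 100),
                                     law$input_units, law$output_units)
    h <- heights_for(cfg_i)
    if (is.null(observed)) {
      data.frame(perturbation_pct = pct,
                 median_height_change_pct = stats::median(
                   100 * (h - base_h) / base_h, na.rm = TRUE))
    } else {
      data.frame(perturbation_pct = pct,
                 median_relative_error = stats::median(
                   relative_error(h, observed), na.rm = TRUE))
    }
  })
  do.call(rbind, rows)
}

#' Signed relative error of a height prediction
#'
#' `(predicted - observed) / observed`; signed, so over- and
#' under-prediction can be distinguished before taking absolute values.
#'
#' @param predicted Predicted height(s), m.
#' @param observed Observed height(s), m, positive.
#'
#' @return Dimensionless signed relative error(s).
#' @export
#' @examples
#' relative_error(15, 20) # -0.25
relative_error <- function(predicted, observed) {
  if (!is.numeric(observed) || any(!is.na(observed) & observed <= 0)) {
    stop("relative_error: 'observed' must be positive", call. = FALSE)
  }
  (predicted - observed) / observed
}
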