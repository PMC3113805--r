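# Trait optimization: invert the framework to find the trait value that
# maximizes the height upper bound in a given climate, all other traits
# held at their average values. Trait-environment trends (lower optimal
# stomatal density and smaller optimal leaves in hotter climates) come
# out of the same constraint chain that sets maximum height.

# Golden-section maximization of f on [lo, hi] to width tol, run only
# inside the bracket produced by the coarse scan (unimodality is not
# assumed globally). Ties break toward the lower endpoint.
golden_section_max <- function(f, lo, hi, tol) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 >= f2) {  # >= keeps the lower interval on ties
      hi <- x2
      x2 <- x1
      f2 <- f1
      x1 <- hi - phi * (hi - lo)
      f1 <- f(x1)
    } else {
      lo <- x1
      x1 <- x2
      f1 <- f2
      x2 <- lo + phi * (hi - lo)
      f2 <- f(x2)
    }
  }
  x <- if (f1 >= f2) x1 else x2
  list(x = x, value = max(f1, f2))
}

# Shared engine: maximize max_height over one numeric trait field.
optimize_trait_field <- function(field, env, traits, params, cfg, bounds,
                                 mode, n_grid, tol, constants, ...) {
  if (!is.numeric(bounds) || length(bounds) != 2L || any(bounds <= 0) ||
      bounds[1] > bounds[2]) {
    stop("trait optimization: 'bounds' must be a positive (min, max) pair",
         call. = FALSE)
  }
  objective <- function(value) {
    tr <- traits
    tr[[field]] <- value
    res <- max_height(env, tr, params, cfg, mode = mode,
                      constants = constants, ...)
    if (is.na(res$max_height)) -Inf else res$max_height
  }
  if (bounds[1] == bounds[2]) {
    h <- objective(bounds[1])
    return(list(optimum = bounds[1],
                max_height = if (is.finite(h)) h else NA_real_,
                infeasible = !is.finite(h),
                scan = data.frame(value = bounds[1],
                                  max_height = if (is.finite(h)) h else NA_real_)))
  }
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  h_grid <- vapply(grid, objective, numeric(1))
  scan <- data.frame(value = grid,
                     max_height = ifelse(is.finite(h_grid), h_grid, NA_real_))
  if (all(!is.finite(h_grid))) {
    return(list(optimum = NA_real_, max_height = NA_real_, infeasible = TRUE,
                scan = scan))
  }
  best <- which(h_grid == max(h_grid))[1]  # ties toward lower value
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(n_grid, best + 1L)]
  refined <- golden_section_max(objective, lo, hi, tol)
  # keep whichever of (scan best, refined) is taller; lower value on ties
  cands <- data.frame(value = c(grid[best], refined$x),
                      h = c(h_grid[best], refined$value))
  cands <- cands[order(-cands$h, cands$value), ]
  list(optimum = cands$value[1], max_height = cands$h[1], infeasible = FALSE,
       scan = scan)
}

#' Environment-optimal stomatal density
#'
#' Finds the stomatal density (leaf-side average) that maximizes the
#' maximum sustainable height in the given climate, all other traits
#' fixed: a coarse scan over the bounds followed by golden-section
#' refinement inside the bracketing interval. Denser stomata pump more
#' water — helpful where energy limits evaporation, harmful where the
#' precipitation supply binds — so the optimum tracks the climate.
#'
#' @param env A [met_environment()].
#' @param traits A [trait_set()] providing every other trait.
#' @param params A [water_budget_params()].
#' @param cfg An [allometry_config()].
#' @param bounds `(min, max)` densities to search, stomata/mm^2.
#' @param mode Constraint chain for the objective; the default
#'   `"both"` keeps the water ceiling active, which is what makes the
#'   optimum finite.
#' @param n_grid Coarse-scan points.
#' @param tol Refinement tolerance, stomata/mm^2.
#' @param constants See [energy_constants()].
#' @param ... Further arguments to [max_height()].
#'
#' @return A list: `optimum` (stomata/mm^2, `NA` if no density in
#'   bounds is feasible), `max_height` (m), `infeasible`, and `scan`
#'   (the coarse-scan table).
#' @export
#' @examples
#' env <- met_environment(1, 15, 0.55, 3, 250)
#' optimal_stomatal_density(env, trait_set(), water_budget_params(),
#'                          allometry_config(), bounds = c(20, 600))
optimal_stomatal_density <- function(env, traits, params, cfg,
                                     bounds = c(20, 600),
                                     mode = c("both", "metabolic_only"),
                                     n_grid = 64, tol = 0.1,
                                     constants = energy_constants(), ...) {
  mode <- match.arg(mode)
  optimize_trait_field("stomatal_density", env, traits, params, cfg, bounds,
                       mode, n_grid, tol, constants, ...)
}

#' Environment-optimal leaf size
#'
#' As [optimal_stomatal_density()], with the characteristic leaf
#' dimension as the free trait. Leaf size sets the boundary-layer
#' conductances: small leaves are tightly coupled to air temperature,
#' large leaves decouple and run hotter or cooler than the air.
#'
#' @inheritParams optimal_stomatal_density
#' @param bounds `(min, max)` leaf dimensions to search, m.
#' @param tol Refinement tolerance, m.
#'
#' @return A list as in [optimal_stomatal_density()], with `optimum`
#'   in m.
#' @export
optimal_leaf_size <- function(env, traits, params, cfg,
                              bounds = c(0.005, 0.3),
                              mode = c("both", "metabolic_only"),
                              n_grid = 64, tol = 1e-4,
                              constants = energy_constants(), ...) {
  mode <- match.arg(mode)
  optimize_trait_field("leaf_characteristic_dimension", env, traits, params,
                       cfg, bounds, mode, n_grid, tol, constants, ...)
}
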