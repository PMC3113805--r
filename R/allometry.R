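# Allometric scaling layer: power laws linking tree dimensions and the
# basal metabolic flow requirement to overall size.

#' Create a power-law scaling relation
#'
#' The atom of the allometric layer: `y = prefactor * x^exponent`, with
#' unit metadata carried alongside so configurations stay auditable.
#'
#' @param prefactor Positive normalization constant, in `output_units`
#'   per `input_units^exponent`.
#' @param exponent Scaling exponent (any real; 0 gives a constant law).
#' @param input_units,output_units Unit labels, e.g. `"cm"`, `"m"`.
#'
#' @return An object of class `scaling_law`.
#' @seealso [evaluate_law()], [fit_scaling_law()], [allometry_config()]
#' @export
#' @examples
#' law <- scaling_law(2, 1.5, "cm", "m")
#' evaluate_law(law, 4)
scaling_law <- function(prefactor, exponent, input_units = "", output_units = "") {
  stopifnot(is.numeric(prefactor), length(prefactor) == 1L,
            is.numeric(exponent), length(exponent) == 1L)
  if (!is.finite(prefactor) || prefactor <= 0) {
    stop("scaling_law: 'prefactor' must be a positive finite number, got ",
         prefactor, call. = FALSE)
  }
  if (!is.finite(exponent)) {
    stop("scaling_law: 'exponent' must be finite", call. = FALSE)
  }
  structure(
    list(prefactor = as.numeric(prefactor), exponent = as.numeric(exponent),
         input_units = as.character(input_units),
         output_units = as.character(output_units)),
    class = "scaling_law"
  )
}

#' @export
print.scaling_law <- function(x, ...) {
  cat(sprintf("<scaling_law> y = %g * x^%g  [%s -> %s]\n",
              x$prefactor, x$exponent, x$input_units, x$output_units))
  invisible(x)
}

#' Evaluate a scaling law
#'
#' @param law A [scaling_law()].
#' @param x Positive numeric vector, in the law's input units.
#'
#' @return `prefactor * x^exponent`, in the law's output units.
#' @export
#' @examples
#' evaluate_law(scaling_law(2, 1.5), 4) # 16
evaluate_law <- function(law, x) {
  stopifnot(inherits(law, "scaling_law"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf(
      "evaluate_law: input to law [%s -> %s] must be positive and finite",
      law$input_units, law$output_units), call. = FALSE)
  }
  law$prefactor * x^law$exponent
}

# Invert y = c * x^a for x; error when a == 0 (constant laws have no inverse).
invert_law <- function(law, y) {
  stopifnot(inherits(law, "scaling_law"))
  if (law$exponent == 0) {
    stop(sprintf(
      "cannot invert constant scaling law [%s -> %s] (exponent is 0)",
      law$input_units, law$output_units), call. = FALSE)
  }
  if (!is.numeric(y) || any(!is.finite(y)) || any(y <= 0)) {
    stop("invert_law: values must be positive and finite", call. = FALSE)
  }
  (y / law$prefactor)^(1 / law$exponent)
}

#' Fit a power law by log-log least squares
#'
#' Ordinary least squares of `log(y)` on `log(x)`; the slope is the
#' exponent and the exponentiated intercept the prefactor. Used for
#' recalibrating any shipped scaling relation against user data.
#'
#' @param x,y Positive numeric vectors of equal length (at least two
#'   points with at least two distinct `x`).
#' @param input_units,output_units Unit labels for the fitted law.
#'
#' @return A [scaling_law()].
#' @export
#' @examples
#' x <- c(1, 2, 4, 8)
#' fit_scaling_law(x, 2 * x^1.5)
fit_scaling_law <- function(x, y, input_units = "", output_units = "") {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("fit_scaling_law: 'x' and 'y' must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("fit_scaling_law: need at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    stop("fit_scaling_law: all points must be positive and finite", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("fit_scaling_law: need at least 2 distinct x values", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, log(x)), log(y))
  scaling_law(exp(fit$coefficients[[1]]), fit$coefficients[[2]],
              input_units, output_units)
}

#' Assemble the allometric configuration of the idealized tree
#'
#' Bundles every scaling relation the model needs: the height-diameter
#' law, the two-regime basal-flow laws with their crossover diameter,
#' canopy radius and depth, lateral root extent, leaf count, and the
#' area of a single leaf. Defaults are the package's calibration values
#' (see the methods vignette); every run should log its resolved
#' configuration, which [write_allometry_config()] supports.
#'
#' The basal metabolic requirement uses `basal_flow_small` below
#' `crossover_diameter` and `basal_flow_large` above it (hard switch).
#' Construction warns when the two laws disagree by more than 5% at the
#' crossover.
#'
#' @param height_vs_diameter Law giving height (m) from trunk diameter
#'   (cm); default exponent 2/3 (elastic similarity for large trees).
#' @param basal_flow_small,basal_flow_large Laws giving the basal
#'   metabolic flow (liters/day) from diameter (cm) below/above the
#'   crossover.
#' @param crossover_diameter Diameter (cm) at which the basal-flow
#'   regime switches.
#' @param canopy_radius,canopy_depth,root_radius Laws giving canopy
#'   radius, canopy depth and lateral root extent (m) from height (m).
#' @param leaf_count Law giving leaf number from trunk diameter (cm).
#' @param leaf_area_single One-sided area of a single leaf, m^2.
#'
#' @return An object of class `allometry_config`.
#' @seealso [geometry_from_height()], [basal_flow()],
#'   [read_allometry_config()]
#' @export
#' @examples
#' cfg <- allometry_config()
#' geometry_from_height(30, cfg)
allometry_config <- function(
    height_vs_diameter = scaling_law(2.0, 2 / 3, "cm", "m"),
    basal_flow_small = scaling_law(0.00266, 2.5, "cm", "liters/day"),
    basal_flow_large = scaling_law(0.006, 2.2, "cm", "liters/day"),
    crossover_diameter = 15,
    canopy_radius = scaling_law(0.1, 1.1, "m", "m"),
    canopy_depth = scaling_law(0.5, 1.0, "m", "m"),
    root_radius = scaling_law(0.2, 1.1, "m", "m"),
    leaf_count = scaling_law(50, 2.0, "cm", "count"),
    leaf_area_single = 0.0015) {
  laws <- list(height_vs_diameter = height_vs_diameter,
               basal_flow_small = basal_flow_small,
               basal_flow_large = basal_flow_large,
               canopy_radius = canopy_radius,
               canopy_depth = canopy_depth,
               root_radius = root_radius,
               leaf_count = leaf_count)
  for (nm in names(laws)) {
    if (!inherits(laws[[nm]], "scaling_law")) {
      stop("allometry_config: '", nm, "' must be a scaling_law", call. = FALSE)
    }
  }
  if (!is.numeric(crossover_diameter) || length(crossover_diameter) != 1L ||
      !is.finite(crossover_diameter) || crossover_diameter <= 0) {
    stop("allometry_config: 'crossover_diameter' must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(leaf_area_single) || length(leaf_area_single) != 1L ||
      !is.finite(leaf_area_single) || leaf_area_single <= 0) {
    stop("allometry_config: 'leaf_area_single' must be a positive number",
         call. = FALSE)
  }
  cfg <- structure(
    c(laws, list(crossover_diameter = as.numeric(crossover_diameter),
                 leaf_area_single = as.numeric(leaf_area_single))),
    class = "allometry_config"
  )
  lo <- evaluate_law(cfg$basal_flow_small, crossover_diameter)
  hi <- evaluate_law(cfg$basal_flow_large, crossover_diameter)
  if (abs(lo - hi) / hi > 0.05) {
    warning(sprintf(
      paste0("allometry_config: basal-flow laws disagree by %.1f%% at the ",
             "crossover diameter (%.3g vs %.3g liters/day at %g cm)"),
      100 * abs(lo - hi) / hi, lo, hi, crossover_diameter), call. = FALSE)
  }
  cfg
}

#' @export
print.allometry_config <- function(x, ...) {
  cat("<allometry_config>\n")
  for (nm in c("height_vs_diameter", "basal_flow_small", "basal_flow_large",
               "canopy_radius", "canopy_depth", "root_radius", "leaf_count")) {
    cat(sprintf("  %-20s y = %g * x^%g  [%s -> %s]\n", nm,
                x[[nm]]$prefactor, x[[nm]]$exponent,
                x[[nm]]$input_units, x[[nm]]$output_units))
  }
  cat(sprintf("  crossover_diameter   %g cm\n", x$crossover_diameter))
  cat(sprintf("  leaf_area_single     %g m^2\n", x$leaf_area_single))
  invisible(x)
}

#' Trunk diameter from height
#'
#' Inverts the configured height-diameter law; the round trip through
#' the forward law is exact to numerical precision.
#'
#' @param h Height(s), m, positive.
#' @param cfg An [allometry_config()].
#'
#' @return Trunk diameter(s), cm.
#' @export
#' @examples
#' cfg <- allometry_config(height_vs_diameter = scaling_law(1, 2 / 3, "cm", "m"))
#' diameter_from_height(4, cfg) # 8
diameter_from_height <- function(h, cfg) {
  stopifnot(inherits(cfg, "allometry_config"))
  invert_law(cfg$height_vs_diameter, h)
}

#' All size-derived dimensions of the idealized tree
#'
#' Evaluates every configured scaling relation at the given height(s):
#' trunk diameter, canopy radius and depth, lateral root extent, leaf
#' count, total one-sided leaf area, projected canopy area, and leaf
#' area index (LAI, total leaf area per projected ground area).
#'
#' @inheritParams diameter_from_height
#'
#' @return A data frame of class `tree_geometry` with one row per
#'   height and columns `height`, `trunk_diameter`, `canopy_radius`,
#'   `canopy_depth`, `root_radius`, `leaf_count`, `total_leaf_area`,
#'   `projected_canopy_area`, `leaf_area_index`.
#' @export
#' @examples
#' geometry_from_height(c(10, 30, 60), allometry_config())
geometry_from_height <- function(h, cfg) {
  stopifnot(inherits(cfg, "allometry_config"))
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0)) {
    stop("geometry_from_height: 'h' must be positive and finite", call. = FALSE)
  }
  d <- diameter_from_height(h, cfg)
  r_can <- evaluate_law(cfg$canopy_radius, h)
  n_leaf <- evaluate_law(cfg$leaf_count, d)
  total_leaf_area <- n_leaf * cfg$leaf_area_single
  a_proj <- pi * r_can^2
  geom <- data.frame(
    height = h,
    trunk_diameter = d,
    canopy_radius = r_can,
    canopy_depth = evaluate_law(cfg$canopy_depth, h),
    root_radius = evaluate_law(cfg$root_radius, h),
    leaf_count = n_leaf,
    total_leaf_area = total_leaf_area,
    projected_canopy_area = a_proj,
    leaf_area_index = total_leaf_area / a_proj
  )
  class(geom) <- c("tree_geometry", "data.frame")
  geom
}

#' Basal metabolic flow requirement
#'
#' The minimum internal water flow (liters/day) needed to support basal
#' metabolism at a given trunk diameter: an empirical two-regime power
#' law in diameter, switching laws at the configured crossover.
#'
#' @param d Trunk diameter(s), cm, positive.
#' @param cfg An [allometry_config()].
#'
#' @return Flow requirement(s), liters/day.
#' @export
#' @examples
#' basal_flow(c(5, 15, 50), allometry_config())
basal_flow <- function(d, cfg) {
  stopifnot(inherits(cfg, "allometry_config"))
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("basal_flow: 'd' must be positive and finite", call. = FALSE)
  }
  small <- evaluate_law(cfg$basal_flow_small, d)
  large <- evaluate_law(cfg$basal_flow_large, d)
  ifelse(d < cfg$crossover_diameter, small, large)
}
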