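# YAML (de)serialization of the allometric configuration, with strict
# schema validation so a run's resolved config can be logged and reused.

LAW_KEYS <- c("prefactor", "exponent", "input_units", "output_units")
CONFIG_LAWS <- c("height_vs_diameter", "basal_flow_small", "basal_flow_large",
                 "canopy_radius", "canopy_depth", "root_radius", "leaf_count")
CONFIG_SCALARS <- c("crossover_diameter", "leaf_area_single")

law_from_list <- function(x, name) {
  if (!is.list(x)) {
    stop("config: section '", name, "' must be a mapping with keys ",
         paste(LAW_KEYS, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(LAW_KEYS, names(x))
  extra <- setdiff(names(x), LAW_KEYS)
  if (length(missing)) {
    stop("config: section '", name, "' is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(extra)) {
    stop("config: section '", name, "' has unknown key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  scaling_law(x$prefactor, x$exponent, x$input_units, x$output_units)
}

#' Read an allometric configuration from YAML
#'
#' The file has one mapping per scaling law (keys `prefactor`,
#' `exponent`, `input_units`, `output_units`) plus the scalars
#' `crossover_diameter` and `leaf_area_single`. Missing or unknown keys
#' are rejected. The shipped default lives at
#' `system.file("extdata", "allometry-default.yaml", package = "treelim")`.
#'
#' @param path Path to a YAML configuration file.
#'
#' @return An [allometry_config()].
#' @export
#' @examples
#' path <- system.file("extdata", "allometry-default.yaml", package = "treelim")
#' read_allometry_config(path)
read_allometry_config <- function(path) {
  raw <- yaml::read_yaml(path)
  expected <- c(CONFIG_LAWS, CONFIG_SCALARS)
  missing <- setdiff(expected, names(raw))
  extra <- setdiff(names(raw), expected)
  if (length(missing)) {
    stop("config: missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("config: unknown section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  laws <- lapply(CONFIG_LAWS, function(nm) law_from_list(raw[[nm]], nm))
  names(laws) <- CONFIG_LAWS
  do.call(allometry_config, c(laws, raw[CONFIG_SCALARS]))
}

#' Write an allometric configuration to YAML
#'
#' Serializes a configuration in the schema [read_allometry_config()]
#' accepts; intended for logging the resolved configuration of a run.
#'
#' @param cfg An [allometry_config()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_allometry_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "allometry_config"))
  out <- lapply(cfg[CONFIG_LAWS], function(law) {
    list(prefactor = law$prefactor, exponent = law$exponent,
         input_units = law$input_units, output_units = law$output_units)
  })
  out <- c(out, cfg[CONFIG_SCALARS])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
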