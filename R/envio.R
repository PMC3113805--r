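# Meteorology ingestion, derived variables, and the synthetic
# site-climatology generator. All meteorology is a long-term annual mean.

ENV_FIELDS <- c("site_id", "precipitation", "air_temperature",
                "relative_humidity", "wind_speed", "solar_radiation",
                "air_pressure")

# CSV schema (column -> internal field). Documented in read_sites().
SITE_COLUMNS <- c(site_id = "site_id", precip_m_yr = "precipitation",
                  tair_c = "air_temperature", rh_frac = "relative_humidity",
                  wind_m_s = "wind_speed", solar_w_m2 = "solar_radiation",
                  pressure_kpa = "air_pressure")

#' One site's long-term-mean meteorology
#'
#' @param precipitation Mean precipitation rate, m/yr.
#' @param air_temperature Mean air temperature, degrees C.
#' @param relative_humidity Mean relative humidity, fraction in (0, 1].
#' @param wind_speed Mean wind speed, m/s.
#' @param solar_radiation Mean incoming shortwave radiation normal to
#'   the ground, W/m^2.
#' @param air_pressure Air pressure, kPa.
#' @param site_id Site label.
#'
#' @return An object of class `met_environment`.
#' @export
#' @examples
#' met_environment(precipitation = 1.2, air_temperature = 12,
#'                 relative_humidity = 0.65, wind_speed = 3,
#'                 solar_radiation = 220)
met_environment <- function(precipitation, air_temperature, relative_humidity,
                            wind_speed, solar_radiation,
                            air_pressure = 101.325, site_id = "site") {
  num <- list(precipitation = precipitation, air_temperature = air_temperature,
              relative_humidity = relative_humidity, wind_speed = wind_speed,
              solar_radiation = solar_radiation, air_pressure = air_pressure)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("met_environment: '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (precipitation < 0) stop("met_environment: precipitation must be >= 0",
                              call. = FALSE)
  if (relative_humidity <= 0 || relative_humidity > 1) {
    stop("met_environment: relative_humidity must be in (0, 1]", call. = FALSE)
  }
  if (wind_speed < 0) stop("met_environment: wind_speed must be >= 0",
                           call. = FALSE)
  if (solar_radiation < 0) stop("met_environment: solar_radiation must be >= 0",
                                call. = FALSE)
  if (air_pressure <= 0) stop("met_environment: air_pressure must be > 0",
                              call. = FALSE)
  structure(c(list(site_id = as.character(site_id)),
              lapply(num, as.numeric)),
            class = "met_environment")
}

#' @export
print.met_environment <- function(x, ...) {
  cat(sprintf(paste0("<met_environment> %s: P = %g m/yr, T = %g C, ",
                     "RH = %g, u = %g m/s, S = %g W/m^2, p = %g kPa\n"),
              x$site_id, x$precipitation, x$air_temperature,
              x$relative_humidity, x$wind_speed, x$solar_radiation,
              x$air_pressure))
  invisible(x)
}

#' Relative humidity from dewpoint and the daily temperature range
#'
#' Long-term-mean RH as the ratio of saturation vapor pressure at the
#' dewpoint to saturation vapor pressure at the mean of the daily
#' minimum and maximum temperatures, clipped to (0, 1].
#'
#' @param t_dew Mean dewpoint temperature, degrees C.
#' @param t_min,t_max Mean daily minimum and maximum temperature,
#'   degrees C.
#'
#' @return Relative humidity, fraction in (0, 1]. A dewpoint above
#'   `t_max` triggers a warning and the result is clipped to 1.
#' @export
#' @examples
#' rh_from_dewpoint(10, 20, 20) # ~0.525
rh_from_dewpoint <- function(t_dew, t_min, t_max) {
  if (any(t_dew > t_max)) {
    warning("rh_from_dewpoint: dewpoint above t_max; result clipped to 1",
            call. = FALSE)
  }
  rh <- saturation_vapor_pressure(t_dew) /
    saturation_vapor_pressure((t_min + t_max) / 2)
  pmin(rh, 1)
}

#' Specification for a synthetic set of site climatologies
#'
#' Defines the envelope of long-term-mean meteorology the generator
#' samples, spanning wet/cool through arid/hot regimes. In `"transect"`
#' mode the sites interpolate jointly ordered gradients (first site
#' wettest/coolest, last driest/hottest) so water- and energy-limited
#' regimes both occur; in `"independent"` mode each variable is drawn
#' uniformly within its range.
#'
#' @param n_sites Number of sites (>= 1).
#' @param precipitation_range Range, m/yr.
#' @param temperature_range Range, degrees C.
#' @param rh_range Range, fraction.
#' @param wind_range Range, m/s.
#' @param solar_range Range, W/m^2.
#' @param correlation_mode `"transect"` or `"independent"`.
#' @param air_pressure Pressure assigned to every site, kPa.
#' @param seed Integer seed for the `"independent"` draws.
#'
#' @return An object of class `environment_grid_spec`.
#' @export
environment_grid_spec <- function(n_sites = 16,
                                  precipitation_range = c(0.25, 2.5),
                                  temperature_range = c(4, 28),
                                  rh_range = c(0.25, 0.75),
                                  wind_range = c(2, 4),
                                  solar_range = c(170, 330),
                                  correlation_mode = c("transect", "independent"),
                                  air_pressure = 101.325,
                                  seed = 1L) {
  correlation_mode <- match.arg(correlation_mode)
  ranges <- list(precipitation_range = precipitation_range,
                 temperature_range = temperature_range,
                 rh_range = rh_range, wind_range = wind_range,
                 solar_range = solar_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop("environment_grid_spec: '", nm, "' must be an ordered (lo, hi) pair",
           call. = FALSE)
    }
  }
  if (!is.numeric(n_sites) || n_sites < 1) {
    stop("environment_grid_spec: n_sites must be >= 1", call. = FALSE)
  }
  structure(c(list(n_sites = as.integer(n_sites)), ranges,
              list(correlation_mode = correlation_mode,
                   air_pressure = air_pressure, seed = as.integer(seed))),
            class = "environment_grid_spec")
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate synthetic site climatologies
#'
#' @param spec An [environment_grid_spec()].
#'
#' @return A list of [met_environment()] objects; deterministic for a
#'   fixed spec (including its seed).
#' @export
#' @examples
#' envs <- generate_environments(environment_grid_spec(n_sites = 4))
#' envs[[1]]
generate_environments <- function(spec) {
  stopifnot(inherits(spec, "environment_grid_spec"))
  n <- spec$n_sites
  grad <- function(range, decreasing = FALSE) {
    if (n == 1L) return(mean(range))
    s <- seq(range[1], range[2], length.out = n)
    if (decreasing) rev(s) else s
  }
  if (spec$correlation_mode == "transect") {
    vals <- list(
      precipitation = grad(spec$precipitation_range, decreasing = TRUE),
      air_temperature = grad(spec$temperature_range),
      relative_humidity = grad(spec$rh_range, decreasing = TRUE),
      wind_speed = grad(spec$wind_range),
      solar_radiation = grad(spec$solar_range)
    )
  } else {
    vals <- with_local_seed(spec$seed, list(
      precipitation = stats::runif(n, spec$precipitation_range[1],
                                   spec$precipitation_range[2]),
      air_temperature = stats::runif(n, spec$temperature_range[1],
                                     spec$temperature_range[2]),
      relative_humidity = stats::runif(n, spec$rh_range[1], spec$rh_range[2]),
      wind_speed = stats::runif(n, spec$wind_range[1], spec$wind_range[2]),
      solar_radiation = stats::runif(n, spec$solar_range[1],
                                     spec$solar_range[2])
    ))
  }
  lapply(seq_len(n), function(i) {
    met_environment(precipitation = vals$precipitation[i],
                    air_temperature = vals$air_temperature[i],
                    relative_humidity = vals$relative_humidity[i],
                    wind_speed = vals$wind_speed[i],
                    solar_radiation = vals$solar_radiation[i],
                    air_pressure = spec$air_pressure,
                    site_id = sprintf("site_%03d", i))
  })
}

#' Convert a list of site environments to a data frame
#'
#' @param envs A list of [met_environment()] objects.
#' @return A data frame in the site CSV schema (see [read_sites()]).
#' @export
sites_as_data_frame <- function(envs) {
  stopifnot(is.list(envs), all(vapply(envs, inherits, logical(1),
                                      "met_environment")))
  out <- data.frame(
    site_id = vapply(envs, `[[`, character(1), "site_id"),
    precip_m_yr = vapply(envs, `[[`, numeric(1), "precipitation"),
    tair_c = vapply(envs, `[[`, numeric(1), "air_temperature"),
    rh_frac = vapply(envs, `[[`, numeric(1), "relative_humidity"),
    wind_m_s = vapply(envs, `[[`, numeric(1), "wind_speed"),
    solar_w_m2 = vapply(envs, `[[`, numeric(1), "solar_radiation"),
    pressure_kpa = vapply(envs, `[[`, numeric(1), "air_pressure")
  )
  out
}

#' Read site climatologies from CSV
#'
#' The schema has one row per site with columns `site_id`,
#' `precip_m_yr`, `tair_c`, `rh_frac`, `wind_m_s`, `solar_w_m2`,
#' `pressure_kpa`. The reader is strict: a missing column, a non-finite
#' value, or an RH outside (0, 1] is rejected with an itemized message
#' naming each offending row.
#'
#' When pairing your own tree records with station data, keep station
#' and tree close (the calibration datasets behind models of this kind
#' use at most 100 m of elevation and 4 km of radial distance); no
#' geospatial matching is performed here.
#'
#' @param path CSV file path.
#'
#' @return A list of [met_environment()] objects (empty, with a
#'   warning, for a header-only file).
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(SITE_COLUMNS), names(df))
  if (length(missing)) {
    stop("read_sites: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("read_sites: header-only file, no sites read", call. = FALSE)
    return(list())
  }
  problems <- character(0)
  num_cols <- setdiff(names(SITE_COLUMNS), "site_id")
  for (col in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: non-finite '%s'", bad, col))
    }
  }
  bad_rh <- which(is.finite(df$rh_frac) & (df$rh_frac <= 0 | df$rh_frac > 1))
  if (length(bad_rh)) {
    problems <- c(problems,
                  sprintf("row %d: rh_frac = %g outside (0, 1]",
                          bad_rh, df$rh_frac[bad_rh]))
  }
  if (length(problems)) {
    stop("read_sites: invalid site table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    met_environment(precipitation = df$precip_m_yr[i],
                    air_temperature = df$tair_c[i],
                    relative_humidity = df$rh_frac[i],
                    wind_speed = df$wind_m_s[i],
                    solar_radiation = df$solar_w_m2[i],
                    air_pressure = df$pressure_kpa[i],
                    site_id = df$site_id[i])
  })
}

#' Write site climatologies to CSV
#'
#' Inverse of [read_sites()]: round-tripping preserves every field.
#'
#' @param path Output CSV path.
#' @param envs A list of [met_environment()] objects.
#' @return `path`, invisibly.
#' @export
write_sites <- function(path, envs) {
  utils::write.csv(sites_as_data_frame(envs), path, row.names = FALSE)
  invisible(path)
}

#' Write per-site results to CSV
#'
#' @param path Output CSV path.
#' @param results A data frame of per-site results (e.g. from
#'   [max_height()] applied over sites).
#' @return `path`, invisibly.
#' @export
write_results <- function(path, results) {
  stopifnot(is.data.frame(results))
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
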