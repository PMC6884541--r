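# Plain-text (YAML) experiment configuration.

#' Default experiment configuration
#'
#' The configuration behind the standard two-scenario experiment: a 6,000
#' year, 75-column (150 m) transect driven by the default synthetic climate
#' (mean net rainfall 96.2 cm yr-1, mean air temperature 7.1 degC), with the
#' default ditch plan for the drained scenario and core analysis at the
#' centre-margin midpoint over the 0-200 and 200-600 yr age windows.
#'
#' @param seed Integer seed for the climate driver.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 42L) {
  list(
    run = list(n_years = 6000L, n_cols = 75L, dx = 2, lagg_head = 0.1,
               hydro_substeps = 20L, seed = as.integer(seed)),
    climate = list(mean_rain_cm = 96.2, rain_sd_cm = 10, rain_autocorr = 0.7,
                   mean_temp_c = 7.1, temp_sd_c = 0.5, temp_autocorr = 0.7,
                   pattern_amplitude = 2),
    params = unclass(model_params()),
    ditch = list(depth_m = 0.5, offset_from_margin_m = 10, spacing_m = 12,
                 count = 10L, open_years_before_end = 200L),
    analysis = list(column = "midpoint",
                    windows = list(c(0, 200), c(200, 600)),
                    preindustrial_window = c(150, 1150)))
}

#' Read or write an experiment configuration
#'
#' Configurations are plain YAML mirroring [default_config()]; missing keys
#' fall back to the defaults, unknown or malformed keys are reported with
#' their full paths.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_config()` returns a validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  validate_config(user)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(user) {
  ref <- default_config()
  problems <- character()
  walk <- function(u, r, path) {
    for (nm in names(u)) {
      p <- paste(c(path, nm), collapse = ".")
      if (!nm %in% names(r)) {
        problems <<- c(problems, paste0("unknown key: ", p))
      } else if (is.list(r[[nm]]) && !is.null(names(r[[nm]]))) {
        if (!is.list(u[[nm]])) {
          problems <<- c(problems, paste0("expected a mapping at: ", p))
        } else {
          walk(u[[nm]], r[[nm]], c(path, nm))
        }
      } else if (!nm %in% c("column", "windows", "preindustrial_window") &&
                 !is.numeric(u[[nm]]) && !is.null(u[[nm]])) {
        problems <<- c(problems, paste0("expected a number at: ", p))
      }
    }
  }
  walk(user, ref, character())
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(user)
}

config_climate <- function(config) {
  cc <- config$climate
  annual <- generate_annual_series(
    n_years = config$run$n_years, mean_rain = cc$mean_rain_cm,
    rain_sd = cc$rain_sd_cm, rain_autocorr = cc$rain_autocorr,
    mean_temp = cc$mean_temp_c, temp_sd = cc$temp_sd_c,
    temp_autocorr = cc$temp_autocorr, seed = config$run$seed)
  weekly_climate(annual, sinusoidal_pattern(cc$pattern_amplitude))
}

config_params <- function(config) {
  do.call(model_params, config$params)
}

config_ditch <- function(config) {
  d <- config$ditch
  ditch_plan(depth = d$depth_m, offset_from_margin = d$offset_from_margin_m,
             spacing = d$spacing_m, count = d$count,
             open_years_before_end = d$open_years_before_end)
}
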