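# The two-scenario experiment: natural vs ditch-drained runs under a shared
# climate and seed, with all comparison tables written as CSV.

#' Run the natural-vs-drained experiment
#'
#' Generates the seeded climate driver, runs the natural and ditch-drained
#' scenarios on it, and writes every stage to `out_dir`: the weekly climate
#' (`climate.csv`), per-scenario yearly transect summaries, midpoint virtual
#' cores, accumulation histories and run metadata, a windowed-rate table
#' (`windowed_rates.csv`, one row per scenario and age window), the net
#' carbon-budget table (`budget.csv`) and a comparison report
#' (`comparison.csv`).  The run is deterministic for a given seed.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file ([read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param scenarios Which scenarios to run (default both).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the two `peat_simulation` objects, the
#'   comparison data frame and `out_dir`.
#' @export
run_experiment <- function(config = default_config(), out_dir,
                           scenarios = c("natural", "drained"),
                           quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_path <- file.path(out_dir, "log.txt")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  on_failure <- function(e) {
    # remove partial outputs so a failed run cannot be mistaken for a result
    unlink(out_dir, recursive = TRUE)
    stop(e)
  }

  tryCatch({
    params <- config_params(config)
    climate <- config_climate(config)
    climate_path <- file.path(out_dir, "climate.csv")
    write_climate_csv(climate, climate_path)
    climate_md5 <- unname(tools::md5sum(climate_path))
    logline("seed ", config$run$seed, "; climate written (md5 ", climate_md5, ")")

    plan <- config_ditch(config)
    n_years <- config$run$n_years
    budget_t0 <- as.integer(n_years - plan$open_years_before_end)

    sims <- list()
    for (sc in scenarios) {
      sim <- run_simulation(
        climate, params, n_cols = config$run$n_cols, dx = config$run$dx,
        n_years = n_years, ditch = if (sc == "drained") plan else NULL,
        lagg_head = config$run$lagg_head,
        hydro_substeps = config$run$hydro_substeps,
        budget_from_year = budget_t0, seed = config$run$seed)
      sims[[sc]] <- sim
      sc_dir <- file.path(out_dir, sc)
      dir.create(sc_dir, showWarnings = FALSE)
      write.csv(as.data.frame(sim), file.path(sc_dir, "yearly.csv"),
                row.names = FALSE, quote = FALSE)
      core <- virtual_core(sim, config$analysis$column)
      write.csv(core, file.path(sc_dir, "core.csv"), row.names = FALSE,
                quote = FALSE)
      hist <- apparent_rate_history(core, params$carbon_fraction)
      write.csv(hist, file.path(sc_dir, "history.csv"), row.names = FALSE,
                quote = FALSE)
      yaml::write_yaml(
        list(scenario = sc, seed = config$run$seed,
             climate_md5 = climate_md5,
             windows = lapply(config$analysis$windows, as.numeric),
             params = unclass(params),
             n_years = n_years, n_cols = config$run$n_cols,
             budget_from_year = budget_t0,
             ditch_columns = as.list(sim$ditch_columns),
             max_mass_balance_residual = max(sim$mass_balance_residual)),
        file.path(sc_dir, "run_info.yml"))
      logline(sc, " run done; worst mass-balance residual ",
              format(max(sim$mass_balance_residual), digits = 3))
    }

    comparison <- NULL
    if (all(c("natural", "drained") %in% names(sims))) {
      rates <- do.call(rbind, lapply(names(sims), function(sc) {
        core <- virtual_core(sims[[sc]], config$analysis$column)
        hist <- apparent_rate_history(core, params$carbon_fraction)
        do.call(rbind, lapply(config$analysis$windows, function(w) {
          data.frame(scenario = sc, age_lo = w[1], age_hi = w[2],
                     mean_rate_gC_m2_yr = windowed_mean_rate(hist, w[1], w[2]))
        }))
      }))
      write.csv(rates, file.path(out_dir, "windowed_rates.csv"),
                row.names = FALSE, quote = FALSE)

      budgets <- do.call(rbind, lapply(names(sims), function(sc) {
        b <- net_balance_series(sims[[sc]], config$analysis$column)
        data.frame(scenario = sc, from_year = b$period["from"],
                   to_year = b$period["to"], N = b$N, A_o = b$A_o,
                   C_s = b$C_s, E = b$E, net = b$net)
      }))
      write.csv(budgets, file.path(out_dir, "budget.csv"), row.names = FALSE,
                quote = FALSE)

      comparison <- compare_scenarios(file.path(out_dir, "natural"),
                                      file.path(out_dir, "drained"),
                                      windows = config$analysis$windows)
      write.csv(comparison, file.path(out_dir, "comparison.csv"),
                row.names = FALSE, quote = FALSE)
      logline("comparison written")
    }
    logline(sprintf("experiment finished in %.1f s",
                    as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
    invisible(list(simulations = sims, comparison = comparison,
                   out_dir = out_dir))
  }, error = on_failure)
}

#' Compare a natural and a drained scenario from their output directories
#'
#' Recomputes the comparison report from the raw per-scenario CSV outputs:
#' windowed mean rates, LORCA, final core thickness and thickness of peat
#' younger than 200 years, per scenario.  The two scenarios must have been
#' driven by the same climate series (checked via the recorded climate
#' checksum); otherwise the comparison is refused.
#'
#' @param natural_dir,drained_dir Scenario output directories written by
#'   [run_experiment()].
#' @param windows List of age windows for the rate comparison; defaults to
#'   the windows recorded with the runs.
#' @return A data frame with one row per scenario and one column per
#'   statistic.
#' @export
compare_scenarios <- function(natural_dir, drained_dir, windows = NULL) {
  dirs <- c(natural = natural_dir, drained = drained_dir)
  infos <- lapply(dirs, function(d) yaml::read_yaml(file.path(d, "run_info.yml")))
  if (is.null(windows)) {
    windows <- infos[[1]]$windows
    if (is.null(windows)) windows <- list(c(0, 200), c(200, 600))
    windows <- lapply(windows, as.numeric)
  }
  md5 <- vapply(infos, function(x) x$climate_md5, "")
  if (length(unique(md5)) != 1L) {
    stop("scenario climate series differ (checksums ",
         paste(md5, collapse = " vs "), "); comparison refused",
         call. = FALSE)
  }
  cf <- infos[[1]]$params$carbon_fraction
  rows <- lapply(names(dirs), function(sc) {
    d <- dirs[[sc]]
    core <- read.csv(file.path(d, "core.csv"))
    class(core) <- c("virtual_core", "data.frame")
    hist <- apparent_rate_history(core, cf)
    row <- data.frame(scenario = sc)
    for (w in windows) {
      row[[sprintf("rate_%g_%g", w[1], w[2])]] <-
        windowed_mean_rate(hist, w[1], w[2])
    }
    row$lorca <- lorca(core, cf)
    row$core_thickness_m <- sum(core$thickness)
    row$thickness_lt_200yr_m <- thickness_younger_than(core, 200)
    row
  })
  do.call(rbind, rows)
}
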