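# Full transect simulation: the annual loop over weekly hydrology, annual
# decomposition, litter addition, thin-layer aggregation and (optionally)
# ditch excavation.  The default engine is the compiled core; engine = "r"
# runs the same loop composed from the package's R-level operations and is
# intended for small audits and tests.

#' Run a peatland development simulation
#'
#' Every simulated year: 52 weekly water-table steps are taken (accumulating
#' each cohort's oxic-exposure fraction and the annual mean water-table
#' depth); cohorts then decompose once with those fractions and the year's
#' air temperature; new litter is added as a cohort at the end of the year;
#' and thin saturated layers are aggregated.  If a ditch plan is given, the
#' ditches are excavated at the start of their opening year and stay open.
#'
#' @param climate A [weekly_climate()] object at least as long as the run.
#' @param params A [model_params()].
#' @param n_cols Number of columns (default 75); the last column is the
#'   fixed-head lagg margin and never accumulates peat.
#' @param dx Column spacing, m (default 2).
#' @param n_years Run length, yr; defaults to the climate length.
#' @param ditch A [ditch_plan()] or `NULL` for a natural run.
#' @param lagg_head Water level of the marginal lagg stream above the base, m.
#' @param hydro_substeps Implicit sub-steps per weekly hydrological step.
#' @param budget_from_year Start year of net carbon-budget tracking (cohorts
#'   present at the end of that year are labelled original acrotelm or
#'   catotelm by the year's mean water table; later additions are labelled
#'   new).  Defaults to the year before ditch opening, or `n_years - 200`
#'   for ditchless runs longer than 400 years; set 0 to disable.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   composition of the R-level operations; slow, for small runs).
#' @param pin_water_table If `TRUE`, hold every water table at the peat
#'   surface instead of simulating flow (a fully anoxic diagnostic mode used
#'   for bog-growth limit checks).
#' @param seed Optional integer recorded with the run (the simulation itself
#'   is deterministic; randomness enters only through the climate driver).
#' @return An object of class `peat_simulation`; see [virtual_core()],
#'   [net_balance_series()] and [as.data.frame.peat_simulation()].
#' @export
run_simulation <- function(climate, params = model_params(), n_cols = 75,
                           dx = 2, n_years = NULL, ditch = NULL,
                           lagg_head = 0.1, hydro_substeps = 20,
                           budget_from_year = NULL,
                           engine = c("cpp", "r"),
                           pin_water_table = FALSE, seed = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(climate, "weekly_climate"))
  validate_params(params)
  if (is.null(n_years)) n_years <- nrow(climate$rain_cm)
  if (nrow(climate$rain_cm) < n_years) {
    stop("climate series (", nrow(climate$rain_cm),
         " years) is shorter than the requested run (", n_years, " years)",
         call. = FALSE)
  }

  ditch_cols <- integer()
  open_year <- 0L
  if (!is.null(ditch)) {
    stopifnot(inherits(ditch, "ditch_plan"))
    ditch_cols <- resolve_ditch_columns(ditch, n_cols, dx)
    open_year <- as.integer(n_years - ditch$open_years_before_end + 1)
    if (open_year < 2) stop("ditch opening year falls before the run starts", call. = FALSE)
  }
  if (is.null(budget_from_year)) {
    budget_from_year <- if (open_year > 0) open_year - 1L
    else if (n_years > 400) as.integer(n_years - 200) else 0L
  }
  budget_from_year <- as.integer(budget_from_year)

  raw <- if (engine == "cpp") {
    cpp_simulate(unclass(params), climate$rain_cm, climate$temperature_C,
                 as.integer(n_cols), dx, lagg_head,
                 as.integer(ditch_cols),
                 if (is.null(ditch)) 0 else ditch$depth,
                 open_year, budget_from_year,
                 as.integer(hydro_substeps), as.integer(n_years),
                 isTRUE(pin_water_table))
  } else {
    simulate_transect_r(params, climate, n_cols, dx, lagg_head, ditch_cols,
                        if (is.null(ditch)) 0 else ditch$depth, open_year,
                        budget_from_year, hydro_substeps, n_years,
                        isTRUE(pin_water_table))
  }

  yearly <- raw[c("total_mass", "height", "mean_wtd", "litter", "oxic_loss",
                  "anoxic_loss", "runoff", "excavated")]
  structure(
    list(n_years = as.integer(n_years), n_cols = as.integer(n_cols), dx = dx,
         params = params, ditch = ditch, ditch_columns = ditch_cols,
         ditch_open_year = open_year, lagg_head = lagg_head,
         budget_from_year = budget_from_year, engine = engine, seed = seed,
         yearly = yearly, final = raw$final,
         mass_balance_residual = raw$mass_balance_residual,
         budget = raw$budget),
    class = "peat_simulation")
}

#' @export
print.peat_simulation <- function(x, ...) {
  cat(sprintf("Peat simulation: %d years, %d x %.0f m columns (%s engine)\n",
              x$n_years, x$n_cols, x$dx, x$engine))
  if (length(x$ditch_columns)) {
    cat(sprintf("  drained: %d ditches opened in year %d (columns %s)\n",
                length(x$ditch_columns), x$ditch_open_year,
                paste(x$ditch_columns, collapse = ", ")))
  } else {
    cat("  natural (no ditches)\n")
  }
  mid <- midpoint_column(x$n_cols)
  cat(sprintf("  final midpoint-column height: %.2f m; transect C stock: %.0f g C m-1\n",
              x$yearly$height[x$n_years, mid],
              x$params$carbon_fraction * sum(x$yearly$total_mass[x$n_years, ]) * x$dx))
  cat(sprintf("  worst column mass-balance residual: %.2e (relative)\n",
              max(x$mass_balance_residual)))
  invisible(x)
}

#' Yearly transect summary as a data frame
#'
#' @param x A `peat_simulation`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A long data frame with one row per year and column.
#' @export
as.data.frame.peat_simulation <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  vars <- names(x$yearly)
  out <- data.frame(
    year = rep(seq_len(x$n_years), times = x$n_cols),
    column = rep(seq_len(x$n_cols), each = x$n_years))
  for (v in vars) out[[v]] <- as.vector(x$yearly[[v]])
  out
}

# Column index of the centre-margin midpoint (x = n_cols * dx / 2).
midpoint_column <- function(n_cols) {
  as.integer(round(n_cols / 2 + 0.5))
}

resolve_column <- function(sim, column) {
  if (identical(column, "midpoint")) return(midpoint_column(sim$n_cols))
  column <- as.integer(column)
  if (column < 1 || column > sim$n_cols) {
    stop("column index out of range 1..", sim$n_cols, call. = FALSE)
  }
  column
}

#' Extract a virtual peat core from a simulation
#'
#' The end-of-run cohort inventory of one column, expressed as a core: one
#' row per cohort record, base to top, with ages in years before the
#' notional present (the end of the run).  An unmerged annual cohort
#' deposited in year `y` spans ages `[n - y, n - y + 1)`; merged records
#' carry their full age span.
#'
#' @param sim A `peat_simulation`.
#' @param column Column index, or `"midpoint"` (default) for the
#'   centre-margin midpoint.
#' @return A data frame of class `virtual_core` with columns `age_young`,
#'   `age_old`, `age_mid`, `mass`, `initial_mass`, `thickness`.
#' @export
virtual_core <- function(sim, column = "midpoint") {
  stopifnot(inherits(sim, "peat_simulation"))
  i <- resolve_column(sim, column)
  fin <- sim$final[[i]]
  if (length(fin$mass) == 0) {
    stop("column ", i, " holds no peat; no core can be taken", call. = FALSE)
  }
  core <- data.frame(
    age_young = sim$n_years - fin$year_young,
    age_old = sim$n_years - fin$year_old + 1,
    mass = fin$mass,
    initial_mass = fin$initial_mass,
    thickness = fin$mass / sim$params$bulk_density)
  core$age_mid <- (core$age_young + core$age_old) / 2
  core <- core[, c("age_young", "age_old", "age_mid", "mass",
                   "initial_mass", "thickness")]
  attr(core, "n_years") <- sim$n_years
  attr(core, "column") <- i
  class(core) <- c("virtual_core", "data.frame")
  core
}

#' Read a core table from delimited text
#'
#' Accepts field-style core tables with one row per layer (base to top or
#' top to base) and columns `age` (yr BP, layer midpoint or `age_top` /
#' `age_bottom` bounds), `dry_mass_per_area` (g m-2) and either `thickness`
#' (m) or `depth_top` / `depth_bottom` (m).
#'
#' @param path CSV file path.
#' @return A `virtual_core` data frame (see [virtual_core()]).
#' @export
read_core_csv <- function(path) {
  df <- read.csv(path)
  if (!"dry_mass_per_area" %in% names(df)) {
    stop("core CSV needs a dry_mass_per_area column", call. = FALSE)
  }
  if (all(c("age_top", "age_bottom") %in% names(df))) {
    age_young <- pmin(df$age_top, df$age_bottom)
    age_old <- pmax(df$age_top, df$age_bottom)
  } else if ("age" %in% names(df)) {
    age_young <- age_old <- df$age
  } else {
    stop("core CSV needs either an age column or age_top/age_bottom", call. = FALSE)
  }
  thickness <- if ("thickness" %in% names(df)) {
    df$thickness
  } else if (all(c("depth_top", "depth_bottom") %in% names(df))) {
    abs(df$depth_bottom - df$depth_top)
  } else {
    rep(NA_real_, nrow(df))
  }
  core <- data.frame(age_young = age_young, age_old = age_old,
                     age_mid = (age_young + age_old) / 2,
                     mass = df$dry_mass_per_area,
                     initial_mass = rep(NA_real_, nrow(df)),
                     thickness = thickness)
  core <- core[order(-core$age_mid), ]  # base (oldest) first
  rownames(core) <- NULL
  class(core) <- c("virtual_core", "data.frame")
  core
}
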