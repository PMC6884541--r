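# A peat column is an ordered stack of annual litter cohorts (base -> top)
# with a water table.  These are the elementary operations of the simulator;
# run_simulation() applies the same logic through the compiled core.

#' Create a peat column
#'
#' @param mass Current cohort masses, g m-2, ordered base to top.
#' @param initial_mass Initial (as-deposited) cohort masses, g m-2; defaults
#'   to `mass`.
#' @param year_young,year_old Youngest and oldest deposition year covered by
#'   each record (equal for unmerged annual cohorts).
#' @param year_mean Mass-weighted mean deposition year of each record.
#' @param base Elevation of the impermeable base, m (default 0).
#' @param head Water-table elevation, m.
#' @param fixed Is this a Dirichlet (fixed-head) column, e.g. a lagg stream
#'   or a ditch?
#' @param fixed_head Head value held by a fixed column, m.
#' @param x_position,width Geometry bookkeeping, m.
#' @return An object of class `peat_column`.
#' @export
peat_column <- function(mass = numeric(), initial_mass = mass,
                        year_young = seq_along(mass),
                        year_old = year_young, year_mean = year_young,
                        base = 0, head = base, fixed = FALSE,
                        fixed_head = NA_real_, x_position = NA_real_,
                        width = 2) {
  stopifnot(length(initial_mass) == length(mass),
            length(year_young) == length(mass),
            all(mass >= 0), all(initial_mass >= mass - 1e-12))
  col <- structure(
    list(mass = as.numeric(mass), initial_mass = as.numeric(initial_mass),
         year_young = as.numeric(year_young), year_old = as.numeric(year_old),
         year_mean = as.numeric(year_mean), base = base, head = head,
         fixed = isTRUE(fixed), fixed_head = fixed_head,
         x_position = x_position, width = width),
    class = "peat_column")
  if (col$fixed && !is.finite(col$fixed_head)) {
    stop("a fixed-head column needs a finite fixed_head", call. = FALSE)
  }
  col
}

#' Cohort thicknesses of a column
#'
#' Thickness is diagnostic of mass: `thickness = mass / bulk_density`.
#'
#' @param column A [peat_column()].
#' @param params A [model_params()].
#' @return Numeric vector of cohort thicknesses, m (base to top).
#' @export
cohort_thickness <- function(column, params) {
  column$mass / params$bulk_density
}

#' Cohort hydraulic conductivities of a column
#'
#' Conductivity declines with decomposition as a power of the remaining mass
#' fraction: `k = k_surface * (mass / initial_mass)^k_exponent`.
#'
#' @inheritParams cohort_thickness
#' @return Numeric vector of conductivities, m wk-1.
#' @export
cohort_conductivity <- function(column, params) {
  frac <- ifelse(column$initial_mass > 0 & column$mass > 0,
                 column$mass / column$initial_mass, 0)
  params$k_surface * frac^params$k_exponent
}

#' @rdname cohort_thickness
#' @export
column_height <- function(column, params) {
  sum(cohort_thickness(column, params))
}

#' @rdname cohort_thickness
#' @export
column_mass <- function(column, params) {
  sum(column$mass)
}

#' @export
print.peat_column <- function(x, ...) {
  cat(sprintf("Peat column: %d cohort record(s), total mass %.1f g m-2\n",
              length(x$mass), sum(x$mass)))
  if (x$fixed) cat(sprintf("  fixed head at %.3f m\n", x$fixed_head))
  invisible(x)
}

#' Annual litter production
#'
#' Litter addition responds unimodally to the annual mean water-table depth
#' (a parabola with its maximum at `wtd_optimum`, clamped at zero beyond
#' `wtd_optimum + wtd_range`, and reduced under inundation) and increases
#' monotonically with air temperature through a Q10-style ramp equal to 1 at
#' the reference temperature.
#'
#' @param annual_mean_wtd Annual mean water-table depth below the surface, m;
#'   negative values (ponding) are clamped to zero.
#' @param temperature Annual mean air temperature, degC.
#' @param params A [model_params()].
#' @return Litter production, g m-2 yr-1 (never negative).
#' @export
litter_production <- function(annual_mean_wtd, temperature, params) {
  wtd <- pmax(0, annual_mean_wtd)
  rel <- (wtd - params$wtd_optimum) / params$wtd_range
  g <- pmax(0, 1 - rel^2)
  ramp <- params$production_q10^((temperature - params$ref_temperature) / 10)
  params$max_production * g * ramp
}

#' Decompose the cohorts of a column for one time step
#'
#' Each cohort loses mass exponentially at a rate blended from the oxic and
#' anoxic end-member rates by its oxic-exposure fraction, scaled by a Q10
#' temperature factor:
#' `m <- m * exp(-(f*a_ox + (1-f)*a_an) * q10^((T-T_ref)/10) * dt)`.
#'
#' @param column A [peat_column()].
#' @param oxic_fraction Per-cohort fraction of the step spent above the water
#'   table, in \[0, 1\] (recycled if scalar).
#' @param temperature Air temperature for the step, degC.
#' @param dt Step length, yr.
#' @param params A [model_params()].
#' @return A list with the updated `column` and the step's `oxic_loss` and
#'   `anoxic_loss` (g m-2).
#' @export
decompose_cohorts <- function(column, oxic_fraction, temperature, dt = 1,
                              params = model_params()) {
  n <- length(column$mass)
  f <- rep_len(oxic_fraction, n)
  if (any(f < 0 | f > 1)) stop("oxic fractions must lie in [0, 1]", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  tfac <- params$decay_q10^((temperature - params$ref_temperature) / 10)
  r_ox <- f * params$oxic_decay_rate
  r_an <- (1 - f) * params$anoxic_decay_rate
  alpha <- (r_ox + r_an) * tfac
  loss <- column$mass * (1 - exp(-alpha * dt))
  share <- ifelse(r_ox + r_an > 0, r_ox / (r_ox + r_an), 0)
  column$mass <- column$mass - loss
  list(column = column,
       oxic_loss = sum(loss * share),
       anoxic_loss = sum(loss * (1 - share)))
}

#' Add one year's litter cohort to the top of a column
#'
#' @param column A [peat_column()].
#' @param litter_mass Litter addition, g m-2 (a zero addition is a no-op).
#' @param year Simulation year of deposition.
#' @return The updated column.
#' @export
add_annual_cohort <- function(column, litter_mass, year) {
  if (litter_mass < 0) stop("litter_mass must be >= 0", call. = FALSE)
  if (litter_mass == 0) return(column)
  column$mass <- c(column$mass, litter_mass)
  column$initial_mass <- c(column$initial_mass, litter_mass)
  column$year_young <- c(column$year_young, year)
  column$year_old <- c(column$year_old, year)
  column$year_mean <- c(column$year_mean, year)
  column
}

#' Merge thin adjacent saturated cohorts
#'
#' Adjacent records thinner than `threshold` and lying entirely below the
#' water table are merged bottom-up: masses and initial masses are summed,
#' the deposition year becomes the mass-weighted mean, and the record keeps
#' its full deposition-year span for later age arithmetic.  Records above
#' the water table are never merged, preserving annual age resolution in the
#' near-surface zone the core analysis depends on.  Total column mass and
#' thickness are conserved exactly.
#'
#' @param column A [peat_column()].
#' @param params A [model_params()] (supplies the bulk density).
#' @param threshold Thickness threshold, m (default
#'   `params$aggregation_threshold`).
#' @param water_table Water-table elevation used as the merge ceiling;
#'   defaults to the column's current head.
#' @return The updated column.
#' @export
aggregate_thin_layers <- function(column, params = model_params(),
                                  threshold = params$aggregation_threshold,
                                  water_table = column$head) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  n <- length(column$mass)
  if (n < 2) return(column)
  th <- cohort_thickness(column, params)
  ztop <- column$base + cumsum(th)
  i <- 1L
  while (i < length(column$mass)) {
    th_i <- column$mass[i] / params$bulk_density
    th_j <- column$mass[i + 1] / params$bulk_density
    if (ztop[i + 1] <= water_table && th_i < threshold && th_j < threshold) {
      msum <- column$mass[i] + column$mass[i + 1]
      column$year_mean[i] <- if (msum > 0) {
        (column$mass[i] * column$year_mean[i] +
           column$mass[i + 1] * column$year_mean[i + 1]) / msum
      } else {
        mean(column$year_mean[i:(i + 1)])
      }
      column$mass[i] <- msum
      column$initial_mass[i] <- column$initial_mass[i] + column$initial_mass[i + 1]
      column$year_old[i] <- min(column$year_old[i], column$year_old[i + 1])
      column$year_young[i] <- max(column$year_young[i], column$year_young[i + 1])
      ztop[i] <- ztop[i + 1]
      drop <- i + 1L
      column$mass <- column$mass[-drop]
      column$initial_mass <- column$initial_mass[-drop]
      column$year_young <- column$year_young[-drop]
      column$year_old <- column$year_old[-drop]
      column$year_mean <- column$year_mean[-drop]
      ztop <- ztop[-drop]
      # the merged record may still be thin; retry at the same position
    } else {
      i <- i + 1L
    }
  }
  column
}

#' Excavate a ditch into a column
#'
#' Removes the top `depth` metres of peat (the topmost partially intersected
#' record is split pro-rata by thickness) and converts the column to a
#' fixed-head (Dirichlet) boundary whose water level sits at the new
#' surface, i.e. `depth` below the pre-excavation surface.  The ditch head
#' does not subsequently track subsidence.
#'
#' @param column A [peat_column()].
#' @param depth Ditch depth, m; must be less than the column height (a zero
#'   depth is a no-op).
#' @param params A [model_params()].
#' @return A list with the updated `column` and the `removed_mass` (g m-2).
#' @export
excavate_ditch <- function(column, depth, params = model_params()) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (depth == 0) return(list(column = column, removed_mass = 0))
  height <- column_height(column, params)
  if (depth >= height) {
    stop(sprintf("ditch depth %.3f m is not less than the peat thickness %.3f m",
                 depth, height), call. = FALSE)
  }
  need <- depth
  removed <- 0
  while (need > 1e-15 && length(column$mass) > 0) {
    i <- length(column$mass)
    th <- column$mass[i] / params$bulk_density
    if (th <= need + 1e-15) {
      removed <- removed + column$mass[i]
      need <- need - th
      column$mass <- column$mass[-i]
      column$initial_mass <- column$initial_mass[-i]
      column$year_young <- column$year_young[-i]
      column$year_old <- column$year_old[-i]
      column$year_mean <- column$year_mean[-i]
    } else {
      fr <- need / th
      removed <- removed + column$mass[i] * fr
      column$mass[i] <- column$mass[i] * (1 - fr)
      column$initial_mass[i] <- column$initial_mass[i] * (1 - fr)
      need <- 0
    }
  }
  column$fixed <- TRUE
  column$fixed_head <- column$base + height - depth
  column$head <- column$fixed_head
  list(column = column, removed_mass = removed)
}
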