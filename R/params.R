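# Model parameters and the ditch-drainage plan.

#' Simulation parameters
#'
#' Collects the rate constants and physical properties of the cohort model.
#' The defaults are a calibrated parameter set for a temperate raised bog:
#' under the default synthetic climate (6,000 years, mean net rainfall
#' 96.2 cm yr-1, mean air temperature 7.1 degC) they produce a midpoint core
#' about 3.5 m thick whose apparent carbon-accumulation history shows the
#' characteristic near-surface "hockey stick" (roughly 140 g C m-2 yr-1 in
#' peat younger than 200 years against roughly 30 g C m-2 yr-1 in peat aged
#' 200-600 years, and a millennial-scale rate near 27 g C m-2 yr-1).
#'
#' @param oxic_decay_rate Decay rate of peat above the water table, yr-1.
#' @param anoxic_decay_rate Decay rate of saturated peat, yr-1.  The default
#'   oxic:anoxic ratio is several hundred; ratios of 100 or more are typical
#'   of field estimates.
#' @param decay_q10 Multiplier on decay rates per 10 degC of warming.
#' @param ref_temperature Air temperature at which the temperature factors
#'   equal 1, degC.
#' @param wtd_optimum Water-table depth of maximum litter production, m.
#' @param wtd_range Half-width of the parabolic production response, m;
#'   production falls to zero at `wtd_optimum + wtd_range` and is reduced
#'   (but nonzero) under inundation.
#' @param max_production Litter production at the optimum water-table depth
#'   and reference temperature, g m-2 yr-1.
#' @param production_q10 Multiplier on litter production per 10 degC.
#' @param bulk_density Dry bulk density of peat, g m-3.
#' @param k_surface Hydraulic conductivity of fresh surface litter, m wk-1.
#' @param k_exponent Exponent of the decomposition-conductivity relation
#'   `k = k_surface * (m/m0)^k_exponent`.
#' @param drainable_porosity Specific yield of the peat (dimensionless).
#' @param carbon_fraction Carbon mass fraction of dry peat (default 0.5).
#' @param aggregation_threshold Thickness below which adjacent saturated
#'   cohorts are merged, m (default 2.5e-3).
#' @return A named list of class `model_params`.
#' @export
model_params <- function(oxic_decay_rate = 0.03,
                         anoxic_decay_rate = 8e-5,
                         decay_q10 = 2.0,
                         ref_temperature = 7.1,
                         wtd_optimum = 0.10,
                         wtd_range = 0.50,
                         max_production = 800,
                         production_q10 = 1.3,
                         bulk_density = 1.0e5,
                         k_surface = 100,
                         k_exponent = 3.0,
                         drainable_porosity = 0.3,
                         carbon_fraction = 0.5,
                         aggregation_threshold = 2.5e-3) {
  p <- list(oxic_decay_rate = oxic_decay_rate,
            anoxic_decay_rate = anoxic_decay_rate,
            decay_q10 = decay_q10,
            ref_temperature = ref_temperature,
            wtd_optimum = wtd_optimum,
            wtd_range = wtd_range,
            max_production = max_production,
            production_q10 = production_q10,
            bulk_density = bulk_density,
            k_surface = k_surface,
            k_exponent = k_exponent,
            drainable_porosity = drainable_porosity,
            carbon_fraction = carbon_fraction,
            aggregation_threshold = aggregation_threshold)
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  pos <- c("oxic_decay_rate", "anoxic_decay_rate", "decay_q10",
           "max_production", "bulk_density", "k_surface",
           "aggregation_threshold", "wtd_range")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  if (p$carbon_fraction <= 0 || p$carbon_fraction > 1) {
    stop("carbon_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (p$drainable_porosity <= 0 || p$drainable_porosity >= 1) {
    stop("drainable_porosity must lie in (0, 1)", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Peat simulation parameters\n")
  cat(sprintf("  decay: oxic %.4g yr-1, anoxic %.4g yr-1 (ratio %.0f), Q10 %.2f\n",
              x$oxic_decay_rate, x$anoxic_decay_rate,
              x$oxic_decay_rate / x$anoxic_decay_rate, x$decay_q10))
  cat(sprintf("  litter: max %.0f g m-2 yr-1 at WTD %.2f m (range %.2f m), Q10 %.2f\n",
              x$max_production, x$wtd_optimum, x$wtd_range, x$production_q10))
  cat(sprintf("  peat: bulk density %.3g g m-3, C fraction %.2f\n",
              x$bulk_density, x$carbon_fraction))
  cat(sprintf("  hydraulics: k_surface %.3g m wk-1, exponent %.1f, porosity %.2f\n",
              x$k_surface, x$k_exponent, x$drainable_porosity))
  invisible(x)
}

#' Ditch-drainage plan
#'
#' Describes a set of contour-parallel ditches cut into the transect.  The
#' default plan is ten 0.5-m deep ditches, the first 10 m from the peatland
#' margin and the rest at 12-m intervals, opened for the final 200 years of
#' the run and kept open.
#'
#' @param depth Ditch depth below the pre-excavation peat surface, m.
#' @param offset_from_margin Distance of the first ditch from the margin, m.
#' @param spacing Distance between ditches, m.
#' @param count Number of ditches.
#' @param open_years_before_end Years before the end of the run at which the
#'   ditches are excavated (they stay open to the end).
#' @return A list of class `ditch_plan`.
#' @export
ditch_plan <- function(depth = 0.5, offset_from_margin = 10, spacing = 12,
                       count = 10, open_years_before_end = 200) {
  stopifnot(depth > 0, offset_from_margin > 0, spacing > 0, count >= 1,
            open_years_before_end >= 1)
  structure(list(depth = depth, offset_from_margin = offset_from_margin,
                 spacing = spacing, count = count,
                 open_years_before_end = open_years_before_end),
            class = "ditch_plan")
}

# Map ditch positions (distances from the margin) onto column indices.
resolve_ditch_columns <- function(plan, n_cols, dx) {
  margin_x <- n_cols * dx
  dist <- plan$offset_from_margin + plan$spacing * (seq_len(plan$count) - 1)
  x <- margin_x - dist
  if (any(x <= 0)) {
    stop("ditch plan places ditches outside the transect", call. = FALSE)
  }
  # column centres sit at (i - 0.5) * dx; snap to the nearest centre
  cols <- as.integer(round(x / dx + 0.5))
  cols <- pmax(1L, pmin(n_cols - 1L, cols))
  sort(unique(cols))
}

#' @export
print.ditch_plan <- function(x, ...) {
  cat(sprintf("Ditch plan: %d ditches, %.2f m deep, first %.0f m from the margin, %.0f m apart,\n",
              x$count, x$depth, x$offset_from_margin, x$spacing))
  cat(sprintf("  opened %d years before the end of the run\n", x$open_years_before_end))
  invisible(x)
}
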