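# Core statistics: apparent carbon-accumulation histories, windowed mean
# rates, LORCA, net balance decomposition and thickness-younger-than-age.

#' Apparent carbon-accumulation history of a core
#'
#' For each sequential pair of records (base to top) the apparent rate is
#' half the summed pair mass, converted to carbon and divided by the age
#' difference between the two records:
#' `rate = carbon_fraction * (m_i + m_(i+1)) / 2 / delta_age`.
#' Age differences are taken youngest-to-youngest, so records merged by
#' thin-layer aggregation contribute multi-year denominators.
#'
#' @param core A [virtual_core()] data frame (>= 2 records).
#' @param carbon_fraction Carbon mass fraction of dry peat (default 0.5).
#' @return A data frame of class `accumulation_history` with one row per
#'   pair: `age` (midpoint of the pair, yr BP), `rate` (g C m-2 yr-1) and
#'   `dage` (the pair's age difference, used as the averaging weight).
#' @export
apparent_rate_history <- function(core, carbon_fraction = 0.5) {
  n <- nrow(core)
  if (is.null(n) || n < 2) {
    stop("a core needs at least two records to form an accumulation history",
         call. = FALSE)
  }
  i <- seq_len(n - 1)
  dage <- core$age_young[i] - core$age_young[i + 1]
  if (any(!is.finite(dage)) || any(dage <= 0)) {
    stop("malformed core: ages must strictly decrease from base to top",
         call. = FALSE)
  }
  hist <- data.frame(
    age = (core$age_mid[i] + core$age_mid[i + 1]) / 2,
    rate = carbon_fraction * (core$mass[i] + core$mass[i + 1]) / 2 / dage,
    dage = dage)
  class(hist) <- c("accumulation_history", "data.frame")
  hist
}

#' Windowed mean apparent rate
#'
#' The age-weighted mean of the apparent rates whose midpoint age falls in
#' `[age_lo, age_hi)`; each entry is weighted by the time span it represents,
#' so aggregated (multi-year) records do not dominate annual ones.
#'
#' @param history An [apparent_rate_history()].
#' @param age_lo,age_hi Window bounds, yr BP (`age_lo < age_hi`).
#' @return Mean rate, g C m-2 yr-1.  An empty window raises an error of
#'   class `peatsim_empty_window`.
#' @export
windowed_mean_rate <- function(history, age_lo, age_hi) {
  if (age_lo >= age_hi) stop("age_lo must be below age_hi", call. = FALSE)
  sel <- history$age >= age_lo & history$age < age_hi
  if (!any(sel)) {
    stop(structure(
      class = c("peatsim_empty_window", "error", "condition"),
      list(message = sprintf("no history entries in the age window [%g, %g)",
                             age_lo, age_hi),
           call = sys.call(-1))))
  }
  weighted.mean(history$rate[sel], history$dage[sel])
}

#' Long-term rate of carbon accumulation (LORCA)
#'
#' Total carbon mass per unit area divided by the basal peat age.
#'
#' @param core A [virtual_core()].
#' @param carbon_fraction Carbon mass fraction of dry peat (default 0.5).
#' @return LORCA, g C m-2 yr-1.
#' @export
lorca <- function(core, carbon_fraction = 0.5) {
  if (is.null(nrow(core)) || nrow(core) == 0) {
    stop("cannot compute LORCA of an empty core", call. = FALSE)
  }
  basal_age <- max(core$age_old)
  if (!is.finite(basal_age) || basal_age <= 0) {
    stop("basal age must be positive", call. = FALSE)
  }
  carbon_fraction * sum(core$mass) / basal_age
}

#' Thickness of peat younger than a given age
#'
#' Sums record thicknesses over ages below the cutoff, pro-rata for records
#' whose age span straddles it.
#'
#' @param core A [virtual_core()] with a `thickness` column.
#' @param age_cutoff Age cutoff, yr BP (>= 0).
#' @return Thickness, m.
#' @export
thickness_younger_than <- function(core, age_cutoff) {
  if (age_cutoff < 0) stop("age_cutoff must be >= 0", call. = FALSE)
  span <- pmax(core$age_old - core$age_young, 0)
  overlap <- pmin(core$age_old, age_cutoff) - pmax(core$age_young, 0)
  overlap <- pmax(overlap, 0)
  frac <- ifelse(span > 0, overlap / span,
                 as.numeric(core$age_mid < age_cutoff))
  sum(core$thickness * frac)
}

#' Net carbon balance of one column over the tracked period
#'
#' Decomposes the change in a column's carbon stock over the budget period
#' recorded with the simulation (by default the final 200 years, the
#' ditch-drainage window) into the carbon remaining from new material added
#' after the period start (`N`), decay losses from the original acrotelm
#' (`A_o`, cohorts above the period-start annual-mean water table), decay
#' losses from the original catotelm (`C_s`, cohorts below it), and any
#' excavated mass (`E`).  The decomposition closes exactly:
#' `stock(t1) - stock(t0) = N - A_o - C_s - E`.
#'
#' @param sim A `peat_simulation` run with budget tracking enabled.
#' @param column Column index or `"midpoint"`.
#' @param carbon_fraction Carbon mass fraction; defaults to the run's.
#' @return A list of class `carbon_budget`: `stock` (data frame of yearly
#'   carbon stock, g C m-2, over the whole run), `period`, and the terms
#'   `N`, `A_o`, `C_s`, `E`, `net` (g C m-2).
#' @export
net_balance_series <- function(sim, column = "midpoint",
                               carbon_fraction = sim$params$carbon_fraction) {
  stopifnot(inherits(sim, "peat_simulation"))
  if (is.null(sim$budget)) {
    stop("this simulation was run without budget tracking ",
         "(budget_from_year = 0)", call. = FALSE)
  }
  i <- resolve_column(sim, column)
  cf <- carbon_fraction
  t0 <- sim$budget$from_year
  t1 <- sim$n_years
  stock <- data.frame(year = seq_len(sim$n_years),
                      stock_c = cf * sim$yearly$total_mass[, i])
  out <- list(
    column = i,
    period = c(from = t0, to = t1),
    stock = stock,
    N = cf * sim$budget$new_mass[i],
    A_o = cf * sim$budget$loss_acrotelm[i],
    C_s = cf * sim$budget$loss_catotelm[i],
    E = cf * sim$budget$excavated[i],
    net = cf * (sim$yearly$total_mass[t1, i] - sim$budget$stock_start[i]))
  class(out) <- "carbon_budget"
  out
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat(sprintf("Carbon budget of column %d over years %d-%d (g C m-2):\n",
              x$column, x$period["from"], x$period["to"]))
  cat(sprintf("  new material remaining (N):      %8.1f\n", x$N))
  cat(sprintf("  original acrotelm loss (A_o):    %8.1f\n", x$A_o))
  cat(sprintf("  original catotelm loss (C_s):    %8.1f\n", x$C_s))
  if (x$E > 0) cat(sprintf("  excavated (E):                   %8.1f\n", x$E))
  cat(sprintf("  net stock change:                %8.1f\n", x$net))
  invisible(x)
}
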