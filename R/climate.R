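# Synthetic climate driver: annual net rainfall and air temperature series,
# disaggregated to 52 weekly net-rainfall inputs by a fixed seasonal pattern.

#' Seasonal disaggregation pattern
#'
#' A set of 52 weekly weights that distribute an annual net-rainfall total
#' into weekly depths.  Weights sum to 1; individual weights may be negative
#' for weeks in which evapotranspiration exceeds rainfall.
#'
#' @param weights Numeric vector of 52 dimensionless weekly fractions.
#' @return An object of class `seasonal_pattern`.
#' @seealso [derive_seasonal_pattern()], [sinusoidal_pattern()]
#' @export
seasonal_pattern <- function(weights) {
  if (length(weights) != 52L || !all(is.finite(weights))) {
    stop("a seasonal pattern needs exactly 52 finite weekly weights",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("seasonal pattern weights must sum to 1 (got ",
         format(sum(weights), digits = 12), ")", call. = FALSE)
  }
  structure(as.numeric(weights), class = "seasonal_pattern")
}

#' Derive a seasonal pattern from one year of weekly observations
#'
#' Each weight is the week's share of the annual total, so that multiplying
#' any annual value by the weights yields weekly depths that sum back to the
#' annual value.
#'
#' @param weekly_observations Numeric vector of 52 observed weekly net
#'   rainfall depths (any consistent unit); their sum must be nonzero.
#' @return A [seasonal_pattern()].
#' @examples
#' p <- derive_seasonal_pattern(rep(1, 52))
#' all.equal(unclass(p), rep(1 / 52, 52))
#' @export
derive_seasonal_pattern <- function(weekly_observations) {
  if (length(weekly_observations) != 52L || !all(is.finite(weekly_observations))) {
    stop("weekly observations must be 52 finite values", call. = FALSE)
  }
  tot <- sum(weekly_observations)
  if (tot == 0) {
    stop("weekly observations sum to zero; no pattern can be derived",
         call. = FALSE)
  }
  seasonal_pattern(weekly_observations / tot)
}

#' Sinusoidal default seasonal pattern
#'
#' A smooth annual cycle with a winter net-rainfall surplus and a summer
#' deficit, used when no observed weekly record is supplied.  With
#' `amplitude > 1` the driest mid-summer weeks dip below zero
#' (evapotranspiration exceeding rainfall).
#'
#' @param amplitude Relative amplitude of the seasonal cycle (dimensionless).
#' @param peak_week Week of maximum net rainfall (default mid-winter, week 1).
#' @return A [seasonal_pattern()].
#' @export
sinusoidal_pattern <- function(amplitude = 2, peak_week = 1) {
  w <- seq_len(52)
  # full cosine cycle; the symmetric sample makes the weights sum exactly to 1
  weights <- (1 + amplitude * cos(2 * pi * (w - peak_week + 0.5) / 52)) / 52
  seasonal_pattern(weights)
}

#' Distribute an annual value into 52 weekly depths
#'
#' @param annual_value Annual net rainfall (cm yr-1).
#' @param pattern A [seasonal_pattern()].
#' @return Numeric vector of 52 weekly depths (cm wk-1) summing to
#'   `annual_value`.
#' @export
annual_to_weekly <- function(annual_value, pattern) {
  if (!inherits(pattern, "seasonal_pattern")) pattern <- seasonal_pattern(pattern)
  annual_value * unclass(pattern)
}

#' Generate a synthetic annual climate series
#'
#' Draws AR(1) series for annual net rainfall and air temperature and then
#' shifts each so that its sample mean equals the target mean exactly,
#' mimicking the use of a single fixed climate reconstruction.
#'
#' @param n_years Number of years (default 6000).
#' @param mean_rain Target mean annual net rainfall, cm (default 96.2).
#' @param rain_sd Interannual standard deviation of net rainfall, cm.
#' @param rain_autocorr Lag-1 autocorrelation of net rainfall.
#' @param mean_temp Target mean annual air temperature, degrees C (default 7.1).
#' @param temp_sd Interannual standard deviation of temperature, degrees C.
#' @param temp_autocorr Lag-1 autocorrelation of temperature.
#' @param seed Integer seed; the same seed reproduces the same series.
#' @return A data frame of class `annual_climate` with columns `year`,
#'   `net_rainfall_cm` and `temperature_C`.
#' @export
generate_annual_series <- function(n_years = 6000, mean_rain = 96.2,
                                   rain_sd = 10, rain_autocorr = 0.7,
                                   mean_temp = 7.1, temp_sd = 0.5,
                                   temp_autocorr = 0.7, seed = NULL) {
  if (n_years < 1) stop("n_years must be at least 1", call. = FALSE)
  if (rain_sd < 0 || temp_sd < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (abs(rain_autocorr) >= 1 || abs(temp_autocorr) >= 1) {
    stop("autocorrelations must lie in (-1, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ar1 <- function(n, mean, sd, phi) {
    if (sd == 0) return(rep(mean, n))
    x <- numeric(n)
    innov_sd <- sd * sqrt(1 - phi^2)
    x[1] <- rnorm(1, 0, sd)
    for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + rnorm(1, 0, innov_sd)
    x <- x + (mean - mean(x))  # pin the sample mean to the target exactly
    x
  }
  rain <- ar1(n_years, mean_rain, rain_sd, rain_autocorr)
  temp <- ar1(n_years, mean_temp, temp_sd, temp_autocorr)
  structure(
    data.frame(year = seq_len(n_years), net_rainfall_cm = rain,
               temperature_C = temp),
    class = c("annual_climate", "data.frame"))
}

#' Disaggregate an annual climate series to weekly resolution
#'
#' Applies the same seasonal pattern to every year, so each year's 52 weekly
#' depths sum to that year's annual net rainfall.  Temperature stays at
#' annual resolution.
#'
#' @param annual An `annual_climate` data frame from
#'   [generate_annual_series()] (or any data frame with columns `year`,
#'   `net_rainfall_cm`, `temperature_C`).
#' @param pattern A [seasonal_pattern()]; defaults to [sinusoidal_pattern()].
#' @return An object of class `weekly_climate`: a list with `rain_cm`
#'   (years x 52 matrix, cm wk-1), `temperature_C` (per-year vector) and the
#'   `pattern` used.
#' @export
weekly_climate <- function(annual, pattern = sinusoidal_pattern()) {
  if (!inherits(pattern, "seasonal_pattern")) pattern <- seasonal_pattern(pattern)
  stopifnot(all(c("net_rainfall_cm", "temperature_C") %in% names(annual)))
  rain <- outer(annual$net_rainfall_cm, unclass(pattern))
  colnames(rain) <- sprintf("week_%02d", seq_len(52))
  structure(list(rain_cm = rain,
                 temperature_C = annual$temperature_C,
                 pattern = pattern),
            class = "weekly_climate")
}

#' @export
print.weekly_climate <- function(x, ...) {
  cat("Weekly climate series:", nrow(x$rain_cm), "years x 52 weeks\n")
  cat(sprintf("  mean annual net rainfall: %.2f cm\n", mean(rowSums(x$rain_cm))))
  cat(sprintf("  mean air temperature:     %.2f degC\n", mean(x$temperature_C)))
  invisible(x)
}

#' Write or read a weekly climate series as CSV
#'
#' Long format with columns `year`, `week`, `net_rainfall_cm`,
#' `temperature_C` (the annual temperature repeated across the year's weeks).
#'
#' @param climate A `weekly_climate` object.
#' @param path File path.
#' @return `read_climate_csv()` returns a `weekly_climate`;
#'   `write_climate_csv()` returns `path` invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  stopifnot(inherits(climate, "weekly_climate"))
  n <- nrow(climate$rain_cm)
  df <- data.frame(
    year = rep(seq_len(n), each = 52),
    week = rep(seq_len(52), times = n),
    net_rainfall_cm = as.vector(t(climate$rain_cm)),
    temperature_C = rep(climate$temperature_C, each = 52))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- read.csv(path)
  need <- c("year", "week", "net_rainfall_cm", "temperature_C")
  if (!all(need %in% names(df))) {
    stop("climate CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$year, df$week), ]
  years <- unique(df$year)
  if (nrow(df) != length(years) * 52L) {
    stop("climate CSV must contain 52 weeks for every year", call. = FALSE)
  }
  rain <- matrix(df$net_rainfall_cm, ncol = 52, byrow = TRUE)
  colnames(rain) <- sprintf("week_%02d", seq_len(52))
  temp <- df$temperature_C[df$week == 1]
  structure(list(rain_cm = rain, temperature_C = temp, pattern = NULL),
            class = "weekly_climate")
}
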