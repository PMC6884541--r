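test_that("seasonal pattern derivation normalizes weekly observations", {
  # uniform record -> uniform weights
  p <- derive_seasonal_pattern(rep(3.7, 52))
  expect_equal(unclass(p), rep(1 / 52, 52))

  # one wet week: weights are shares of the annual total
  obs <- c(2, rep(1, 51))
  p2 <- derive_seasonal_pattern(obs)
  expect_equal(p2[1], 2 / 53)
  expect_equal(unclass(p2)[-1], rep(1 / 53, 51))
  expect_equal(sum(p2), 1)

  expect_error(derive_seasonal_pattern(rep(1, 51)), "52")
  expect_error(derive_seasonal_pattern(c(26, -26, rep(0, 50))), "zero")
  expect_error(seasonal_pattern(rep(1, 52)), "sum to 1")
})

test_that("weekly disaggregation conserves the annual total", {
  expect_equal(annual_to_weekly(52, derive_seasonal_pattern(rep(1, 52))),
               rep(1, 52))
  expect_equal(annual_to_weekly(96.2, derive_seasonal_pattern(rep(1, 52))),
               rep(96.2 / 52, 52))

  # a pattern with a negative mid-summer weight still sums back exactly
  w <- rep(1 / 50, 52); w[26] <- w[26] - 2 / 50
  p <- seasonal_pattern(w)
  wk <- annual_to_weekly(80, p)
  expect_lt(wk[26], 0)
  expect_equal(sum(wk), 80)

  # the same property holds for every year of a generated series
  clim <- tiny_climate(50, seed = 3)
  ann <- rowSums(clim$rain_cm)
  expect_equal(ann, generate_annual_series(n_years = 50, seed = 3)$net_rainfall_cm,
               tolerance = 1e-12)
})

test_that("generated series hit the target means exactly and are reproducible", {
  s <- generate_annual_series(n_years = 500, seed = 11)
  expect_equal(mean(s$net_rainfall_cm), 96.2, tolerance = 1e-12)
  expect_equal(mean(s$temperature_C), 7.1, tolerance = 1e-12)
  expect_gt(stats::sd(s$net_rainfall_cm), 0)

  # degenerate variance collapses to constant series at the means
  s0 <- generate_annual_series(n_years = 10, rain_sd = 0, temp_sd = 0)
  expect_equal(s0$net_rainfall_cm, rep(96.2, 10))
  expect_equal(s0$temperature_C, rep(7.1, 10))

  # determinism contract
  expect_identical(generate_annual_series(n_years = 100, seed = 5),
                   generate_annual_series(n_years = 100, seed = 5))

  expect_error(generate_annual_series(n_years = 0), "n_years")
  expect_error(generate_annual_series(rain_sd = -1), "deviations")
  expect_error(generate_annual_series(rain_autocorr = 1), "utocorrelation")
})

test_that("climate CSV round-trips", {
  clim <- tiny_climate(8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(clim, path)
  back <- read_climate_csv(path)
  expect_equal(back$rain_cm, clim$rain_cm, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$temperature_C, clim$temperature_C, tolerance = 1e-12)
})
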