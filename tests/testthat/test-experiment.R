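smoke_config <- function(seed = 5) {
  cfg <- default_config(seed)
  cfg$run$n_years <- 120L
  cfg$run$n_cols <- 10L
  cfg$ditch <- list(depth_m = 0.05, offset_from_margin_m = 3, spacing_m = 4,
                    count = 2L, open_years_before_end = 30L)
  cfg$analysis$windows <- list(c(0, 30), c(30, 90))
  cfg$analysis$preindustrial_window <- c(10, 100)
  cfg
}

test_that("the experiment pipeline writes a complete, self-consistent set of outputs", {
  out <- withr::local_tempdir()
  res <- run_experiment(smoke_config(), out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "climate.csv")))
  for (sc in c("natural", "drained")) {
    for (f in c("yearly.csv", "core.csv", "history.csv", "run_info.yml")) {
      expect_true(file.exists(file.path(out, sc, f)), label = file.path(sc, f))
    }
  }
  for (f in c("windowed_rates.csv", "budget.csv", "comparison.csv", "log.txt")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }

  # budgets close for both scenarios
  bud <- read.csv(file.path(out, "budget.csv"))
  expect_equal(bud$net, bud$N - bud$A_o - bud$C_s - bud$E, tolerance = 1e-8)

  # the comparison report is recomputable from the per-scenario CSVs
  cmp <- read.csv(file.path(out, "comparison.csv"))
  rates <- read.csv(file.path(out, "windowed_rates.csv"))
  for (sc in c("natural", "drained")) {
    expect_equal(cmp$rate_0_30[cmp$scenario == sc],
                 rates$mean_rate_gC_m2_yr[rates$scenario == sc &
                                            rates$age_lo == 0],
                 tolerance = 1e-9)
  }
})

test_that("experiments are bit-reproducible under a fixed seed", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_experiment(smoke_config(), out1, quiet = TRUE)
  run_experiment(smoke_config(), out2, quiet = TRUE)
  for (f in c("climate.csv", "natural/yearly.csv", "drained/yearly.csv",
              "natural/core.csv", "drained/core.csv", "windowed_rates.csv",
              "budget.csv", "comparison.csv")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
})

test_that("comparing a scenario with itself shows no differences", {
  out <- withr::local_tempdir()
  run_experiment(smoke_config(), out, quiet = TRUE)
  cmp <- compare_scenarios(file.path(out, "natural"), file.path(out, "natural"),
                           windows = list(c(0, 30), c(30, 90)))
  num <- vapply(cmp[-1], is.numeric, TRUE)
  for (v in names(cmp[-1])[num]) {
    expect_equal(cmp[[v]][1], cmp[[v]][2], label = v)
  }
})

test_that("comparison is refused when the climates differ", {
  out <- withr::local_tempdir()
  run_experiment(smoke_config(), out, quiet = TRUE)
  info_path <- file.path(out, "drained", "run_info.yml")
  info <- yaml::read_yaml(info_path)
  info$climate_md5 <- "0000deadbeef"
  yaml::write_yaml(info, info_path)
  expect_error(compare_scenarios(file.path(out, "natural"),
                                 file.path(out, "drained")),
               "refused")
})

test_that("config files round-trip and schema violations name their keys", {
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(smoke_config(), path)
  cfg <- read_config(path)
  expect_equal(cfg$run$n_years, 120)
  expect_equal(cfg$ditch$open_years_before_end, 30)

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("run:", "  n_years: 100", "  banana: 3"), bad)
  expect_error(read_config(bad), "run.banana")
  bad2 <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("climate:", "  mean_rain_cm: wet"), bad2)
  expect_error(read_config(bad2), "climate.mean_rain_cm")
})

test_that("failed experiments leave no partial outputs behind", {
  cfg <- smoke_config()
  cfg$params$drainable_porosity <- 2  # invalid; rejected by validation
  out <- file.path(withr::local_tempdir(), "exp")
  expect_error(run_experiment(cfg, out, quiet = TRUE))
  expect_false(dir.exists(out))
})
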