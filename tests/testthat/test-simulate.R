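test_that("no litter production means no peat", {
  clim <- tiny_climate(20)
  # optimum pushed so far dry that the parabola is zero at any wet depth
  p <- model_params(wtd_optimum = 5, wtd_range = 0.5)
  sim <- run_simulation(clim, p, n_cols = 5)
  expect_equal(sum(sim$yearly$total_mass), 0)
})

test_that("an always-anoxic column follows the bog-growth closed form", {
  a <- 0.01
  t_end <- round(5 / a)
  clim <- flat_climate(t_end)
  p <- model_params(wtd_optimum = 0, anoxic_decay_rate = a)
  sim <- run_simulation(clim, p, n_cols = 2, pin_water_table = TRUE)
  mass <- sum(sim$final[[1]]$mass)
  litter <- litter_production(0, p$ref_temperature, p)
  expect_equal(mass, (litter / a) * (1 - exp(-a * t_end)), tolerance = 0.01)
})

test_that("the compiled loop equals the composition of the R-level operations", {
  clim <- tiny_climate(40, seed = 7)
  plan <- ditch_plan(depth = 0.05, offset_from_margin = 3, spacing = 4,
                     count = 2, open_years_before_end = 15)
  for (ditch in list(NULL, plan)) {
    s_cpp <- run_simulation(clim, n_cols = 8, ditch = ditch, engine = "cpp")
    s_r <- run_simulation(clim, n_cols = 8, ditch = ditch, engine = "r")
    for (v in names(s_cpp$yearly)) {
      expect_equal(s_r$yearly[[v]], s_cpp$yearly[[v]], tolerance = 1e-9)
    }
    mid <- 4
    expect_equal(s_r$final[[mid]]$mass, s_cpp$final[[mid]]$mass,
                 tolerance = 1e-9)
    if (!is.null(s_cpp$budget)) {
      expect_equal(s_r$budget, s_cpp$budget, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("simulations are deterministic and respect physical bounds", {
  clim <- tiny_climate(60, seed = 9)
  s1 <- run_simulation(clim, n_cols = 10)
  s2 <- run_simulation(clim, n_cols = 10)
  expect_identical(s1$yearly, s2$yearly)

  # cohort masses never exceed their initial masses
  for (i in seq_len(10)) {
    f <- s1$final[[i]]
    expect_true(all(f$mass <= f$initial_mass + 1e-9))
    expect_true(all(f$mass >= 0))
  }
  # water-table depths are non-negative (heads never rise above the surface)
  expect_true(all(s1$yearly$mean_wtd >= 0))
  # heads end within [base, surface]
  for (i in seq_len(9)) {
    f <- s1$final[[i]]
    expect_gte(f$head, 0)
    expect_lte(f$head, sum(f$mass) / s1$params$bulk_density + 1e-9)
  }

  expect_error(run_simulation(clim, n_years = 100), "shorter")
})

test_that("per-column mass balance closes over whole runs", {
  clim <- tiny_climate(80, seed = 4)
  plan <- ditch_plan(depth = 0.05, offset_from_margin = 3, spacing = 6,
                     count = 2, open_years_before_end = 20)
  sim <- run_simulation(clim, n_cols = 12, ditch = plan)
  expect_lt(max(sim$mass_balance_residual), 1e-6)
  # and explicitly: inputs - decay - excavation = final stock
  for (i in c(1, 6, 12)) {
    lhs <- sum(sim$yearly$litter[, i]) - sum(sim$yearly$oxic_loss[, i]) -
      sum(sim$yearly$anoxic_loss[, i]) - sum(sim$yearly$excavated[, i])
    expect_equal(lhs, sum(sim$final[[i]]$mass), tolerance = 1e-8)
  }
})
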