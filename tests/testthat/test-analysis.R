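make_core <- function(age_young, age_old = age_young, mass,
                      thickness = mass / 1e5) {
  core <- data.frame(age_young = age_young, age_old = age_old,
                     age_mid = (age_young + age_old) / 2, mass = mass,
                     initial_mass = mass, thickness = thickness)
  class(core) <- c("virtual_core", "data.frame")
  core
}

test_that("apparent rates follow the paired-layer formula", {
  # base-to-top pair of annual layers: 0.5 * (100 + 110) / 2 / 1 = 52.5
  core <- make_core(age_young = c(2, 1), age_old = c(3, 2),
                    mass = c(100, 110))
  h <- apparent_rate_history(core)
  expect_equal(h$rate, 52.5)
  expect_equal(h$dage, 1)
  expect_equal(h$age, 2)

  # zero masses give zero rates; carbon fraction scales linearly
  z <- make_core(age_young = c(5, 3, 1), age_old = c(6, 4, 2),
                 mass = c(0, 0, 0))
  expect_equal(apparent_rate_history(z)$rate, c(0, 0))
  c1 <- make_core(age_young = c(5, 3, 1), age_old = c(6, 4, 2),
                  mass = c(30, 20, 10))
  expect_equal(apparent_rate_history(c1, carbon_fraction = 1)$rate,
               2 * apparent_rate_history(c1, carbon_fraction = 0.5)$rate)

  # merged records contribute their multi-year spans as denominators
  m <- make_core(age_young = c(10, 2), age_old = c(20, 3), mass = c(80, 40))
  expect_equal(apparent_rate_history(m)$dage, 8)
  expect_equal(apparent_rate_history(m)$rate, 0.5 * (80 + 40) / 2 / 8)

  expect_error(apparent_rate_history(make_core(1, 2, 10)), "at least two")
  bad <- make_core(age_young = c(1, 1), age_old = c(2, 2), mass = c(1, 1))
  expect_error(apparent_rate_history(bad), "malformed")
})

test_that("windowed means are span-weighted and flag empty windows", {
  h <- structure(data.frame(age = c(150, 60), rate = c(10, 20),
                            dage = c(50, 150)),
                 class = c("accumulation_history", "data.frame"))
  expect_equal(windowed_mean_rate(h, 0, 200), (10 * 50 + 20 * 150) / 200)

  # constant history returns the constant
  hc <- structure(data.frame(age = seq(5, 95, 10), rate = 7,
                             dage = rep(10, 10)),
                  class = c("accumulation_history", "data.frame"))
  expect_equal(windowed_mean_rate(hc, 0, 100), 7)

  expect_error(windowed_mean_rate(h, 300, 400),
               class = "peatsim_empty_window")
  expect_error(windowed_mean_rate(h, 200, 100), "age_lo")
})

test_that("LORCA divides the carbon stock by the basal age", {
  core <- make_core(age_young = c(599, 300, 100), age_old = c(600, 301, 101),
                    mass = c(100, 200, 300))
  expect_equal(lorca(core), 0.5 * 600 / 600)
  one <- make_core(age_young = 400, age_old = 400, mass = 800)
  expect_equal(lorca(one), 0.5 * 800 / 400)
  expect_error(lorca(make_core(numeric(), mass = numeric())), "empty")

  # equivalence with a whole-core windowed mean on annual layers
  ages <- 50:1
  core2 <- make_core(age_young = ages, age_old = ages + 1,
                     mass = seq(60, 10, length.out = 50))
  h <- apparent_rate_history(core2)
  expect_equal(windowed_mean_rate(h, 0, 51), lorca(core2), tolerance = 0.05)
})

test_that("thickness younger than a cutoff selects and pro-rates records", {
  # point-aged records: simple selection
  core <- make_core(age_young = c(250, 150, 50), mass = rep(1e4, 3))
  expect_equal(thickness_younger_than(core, 200), 0.2)
  expect_equal(thickness_younger_than(core, 1000), 0.3)
  expect_equal(thickness_younger_than(core, 0), 0)

  # a record straddling the cutoff contributes pro-rata
  sp <- make_core(age_young = c(150, 0), age_old = c(250, 150),
                  mass = c(1e4, 1e4))
  expect_equal(thickness_younger_than(sp, 200), 0.1 + 0.1 * 50 / 100)
  expect_error(thickness_younger_than(core, -1), ">= 0")
})

test_that("the net balance decomposition closes against the stock change", {
  clim <- tiny_climate(80, seed = 12)
  plan <- ditch_plan(depth = 0.05, offset_from_margin = 3, spacing = 6,
                     count = 2, open_years_before_end = 20)
  sim <- run_simulation(clim, n_cols = 12, ditch = plan)
  for (col in c(2, 6, 10)) {
    b <- net_balance_series(sim, col)
    expect_equal(b$net, b$N - b$A_o - b$C_s - b$E, tolerance = 1e-8)
    expect_gte(b$N, 0); expect_gte(b$A_o, 0); expect_gte(b$C_s, 0)
    # the stock series is consistent with the reported period change
    expect_equal(b$net,
                 b$stock$stock_c[sim$n_years] - b$stock$stock_c[b$period["from"]],
                 tolerance = 1e-9)
  }
  # zero decay and no excavation: the net change is exactly the new material
  p0 <- model_params(oxic_decay_rate = 1e-300, anoxic_decay_rate = 1e-300)
  s0 <- run_simulation(tiny_climate(30, seed = 2), p0, n_cols = 5,
                       budget_from_year = 10)
  b0 <- net_balance_series(s0, 2)
  expect_equal(b0$A_o + b0$C_s, 0, tolerance = 1e-9)
  expect_equal(b0$net, b0$N, tolerance = 1e-9)

  s_nb <- run_simulation(tiny_climate(30, seed = 2), n_cols = 5)
  expect_error(net_balance_series(s_nb, 2), "without budget")
})

test_that("windowed rates are insensitive to thin-layer aggregation", {
  clim <- tiny_climate(900, seed = 21)
  p_on <- model_params()
  p_off <- model_params(aggregation_threshold = 1e-9)
  s_on <- run_simulation(clim, p_on, n_cols = 10)
  s_off <- run_simulation(clim, p_off, n_cols = 10)
  h_on <- apparent_rate_history(virtual_core(s_on))
  h_off <- apparent_rate_history(virtual_core(s_off))
  for (w in list(c(0, 200), c(200, 600))) {
    r_on <- windowed_mean_rate(h_on, w[1], w[2])
    r_off <- windowed_mean_rate(h_off, w[1], w[2])
    expect_lt(abs(r_on - r_off) / r_off, 0.05)
  }
})

test_that("user core tables load into the analysis pipeline", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(depth_top = c(0, 0.1, 0.2),
                       depth_bottom = c(0.1, 0.2, 0.3),
                       age = c(50, 150, 400),
                       dry_mass_per_area = c(3000, 2000, 1500)),
            path, row.names = FALSE)
  core <- read_core_csv(path)
  expect_s3_class(core, "virtual_core")
  expect_equal(core$mass, c(1500, 2000, 3000))  # base first
  h <- apparent_rate_history(core)
  expect_equal(h$rate[1], 0.5 * (1500 + 2000) / 2 / 250)
  expect_equal(lorca(core), 0.5 * 6500 / 400)
})
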