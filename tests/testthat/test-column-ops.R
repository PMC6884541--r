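test_that("litter production is unimodal in water-table depth with a Q10 ramp", {
  p <- model_params()
  ref <- p$ref_temperature

  # maximum at the optimum depth and reference temperature
  expect_equal(litter_production(p$wtd_optimum, ref, p), p$max_production)
  # clamped to zero beyond the outer edge of the parabola
  expect_equal(litter_production(p$wtd_optimum + p$wtd_range + 0.05, ref, p), 0)
  # declines away from the optimum (evaluate the quadratic on both sides)
  expect_lt(litter_production(p$wtd_optimum + 0.3, ref, p),
            litter_production(p$wtd_optimum, ref, p))
  expect_equal(litter_production(p$wtd_optimum + 0.3, ref, p),
               p$max_production * (1 - (0.3 / p$wtd_range)^2))
  # inundation (negative depth clamps to the surface) reduces production
  expect_equal(litter_production(-0.4, ref, p), litter_production(0, ref, p))
  expect_lt(litter_production(0, ref, p), p$max_production)
  # warmer years produce more litter; ramp equals 1 at the reference
  expect_gt(litter_production(p$wtd_optimum, ref + 2, p),
            litter_production(p$wtd_optimum, ref, p))
})

test_that("decomposition follows the blended exponential decay law", {
  p <- model_params(oxic_decay_rate = 0.01, anoxic_decay_rate = 1e-4)
  col <- peat_column(mass = 100, year_young = 1)

  # closed-form oracle: fully oxic cohort, 100 years at 0.01 yr-1
  out <- decompose_cohorts(col, 1, p$ref_temperature, dt = 100, params = p)
  expect_equal(out$column$mass, 100 * exp(-1), tolerance = 1e-12)
  expect_equal(out$oxic_loss, 100 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(out$anoxic_loss, 0)

  # identity cases: dt -> 0, or both rates effectively zero exposure
  out0 <- decompose_cohorts(col, 1, p$ref_temperature, dt = 1e-12, params = p)
  expect_equal(out0$column$mass, 100, tolerance = 1e-9)

  # oxic:anoxic instantaneous loss ratio matches the rate ratio (here 100)
  two <- peat_column(mass = c(50, 50), year_young = 1:2)
  dt <- 1e-4
  res <- decompose_cohorts(two, c(0, 1), p$ref_temperature, dt, params = p)
  loss <- two$mass - res$column$mass
  expect_equal(loss[2] / loss[1], 100, tolerance = 1e-3)

  # mass never increases, for any exposure pattern
  set.seed(42)
  for (i in 1:20) {
    m <- runif(10, 0, 500)
    cc <- peat_column(mass = m, year_young = 1:10)
    r <- decompose_cohorts(cc, runif(10), runif(1, 0, 15), runif(1, 0.1, 5), p)
    expect_true(all(r$column$mass <= m + 1e-12))
    expect_true(all(r$column$mass >= 0))
  }

  expect_error(decompose_cohorts(col, 1.5, 7.1, 1, p), "\\[0, 1\\]")
  expect_error(decompose_cohorts(col, 1, 7.1, 0, p), "dt")
})

test_that("annual cohort addition stacks mass and height", {
  p <- model_params(bulk_density = 1e5)
  col <- peat_column()
  col <- add_annual_cohort(col, 200, 1)
  expect_equal(column_height(col, p), 2e-3)
  expect_equal(col$initial_mass, 200)

  # zero addition is a no-op
  expect_identical(add_annual_cohort(col, 0, 2), col)

  # n years of constant litter with no decay sum exactly
  for (y in 2:10) col <- add_annual_cohort(col, 200, y)
  expect_equal(column_mass(col, p), 10 * 200)
  expect_equal(length(col$mass), 10)
  expect_error(add_annual_cohort(col, -1, 11), ">= 0")
})

test_that("thin-layer aggregation merges saturated thin cohorts and conserves totals", {
  p <- model_params(bulk_density = 1e5)  # threshold 2.5e-3 m = 250 g m-2

  # two adjacent sub-threshold cohorts merge into one with summed mass
  col <- peat_column(mass = c(50, 60, 400), initial_mass = c(500, 500, 400),
                     year_young = 1:3, head = 10)
  out <- aggregate_thin_layers(col, p, water_table = 10)
  expect_equal(out$mass, c(110, 400))
  expect_equal(out$initial_mass, c(1000, 400))
  expect_equal(out$year_old[1], 1)
  expect_equal(out$year_young[1], 2)
  # mass-weighted mean deposition year
  expect_equal(out$year_mean[1], (50 * 1 + 60 * 2) / 110)
  expect_equal(column_mass(out, p), column_mass(col, p))
  expect_equal(column_height(out, p), column_height(col, p))

  # no sub-threshold cohorts -> unchanged
  fat <- peat_column(mass = c(400, 400), year_young = 1:2, head = 10)
  expect_equal(aggregate_thin_layers(fat, p, water_table = 10)$mass, fat$mass)

  # cohorts above the water table are never merged
  dry <- peat_column(mass = c(50, 60), year_young = 1:2, head = 0)
  expect_equal(aggregate_thin_layers(dry, p, water_table = 0)$mass, c(50, 60))

  # after aggregation no run of >= 2 adjacent sub-threshold records remains
  # below the water table
  set.seed(7)
  for (i in 1:20) {
    m <- runif(40, 10, 400)
    cc <- peat_column(mass = m, year_young = 1:40, head = 1)
    ag <- aggregate_thin_layers(cc, p, water_table = 1)
    expect_equal(column_mass(ag, p), sum(m))
    th <- cohort_thickness(ag, p)
    thin <- th < p$aggregation_threshold
    expect_false(any(thin[-length(thin)] & thin[-1]))
    # deposition-year spans stay ordered
    expect_true(all(diff(ag$year_young) > 0))
  }
})

test_that("ditch excavation removes the top pro-rata and fixes the head", {
  p <- model_params(bulk_density = 1e5)
  # two 0.3-m cohorts on a 1-m base stack; a 0.5-m ditch removes the top
  # cohort whole and two-thirds of the next
  col <- peat_column(mass = c(1e5, 3e4, 3e4), year_young = 1:3)
  out <- excavate_ditch(col, 0.5, p)
  expect_equal(out$removed_mass, 3e4 + (0.2 / 0.3) * 3e4)
  expect_equal(column_height(out$column, p), 1.6 - 0.5)
  expect_true(out$column$fixed)
  expect_equal(out$column$fixed_head, 1.6 - 0.5)
  # the split record keeps its decomposition state (mass/initial ratio)
  expect_equal(out$column$mass[2] / out$column$initial_mass[2], 1)

  # identity and error contracts
  expect_equal(excavate_ditch(col, 0, p)$removed_mass, 0)
  expect_error(excavate_ditch(col, 1.6, p), "thickness")
})
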