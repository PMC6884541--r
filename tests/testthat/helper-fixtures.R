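# Shared builders for small test configurations.

tiny_climate <- function(n_years, seed = 1, ...) {
  weekly_climate(generate_annual_series(n_years = n_years, seed = seed, ...))
}

# A constant (variance-free) climate at the default means.
flat_climate <- function(n_years, pattern = sinusoidal_pattern()) {
  weekly_climate(
    generate_annual_series(n_years = n_years, rain_sd = 0, temp_sd = 0),
    pattern)
}

# A uniform single-cohort transect for hydrology tests: homogeneous K and a
# surface high enough that heads never reach it.
uniform_transect <- function(n_cols, dx = 2, k = 10, thickness_m = 10,
                             fixed_head = 1, head = fixed_head,
                             bulk_density = 1e5) {
  cols <- lapply(seq_len(n_cols), function(i) {
    peat_column(mass = thickness_m * bulk_density, head = head,
                x_position = (i - 0.5) * dx)
  })
  cols[[n_cols]]$fixed <- TRUE
  cols[[n_cols]]$fixed_head <- fixed_head
  cols[[n_cols]]$head <- fixed_head
  make_transect(cols, dx)
}

hydro_test_params <- function(k = 10, ...) {
  model_params(k_surface = k, k_exponent = 0, bulk_density = 1e5, ...)
}
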