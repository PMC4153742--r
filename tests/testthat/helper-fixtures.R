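# Small fixtures shared across test files.  Everything is generated in
# code; sizes are kept small so the whole suite runs quickly.

small_region <- function(n_stations = 6L, n_years = 1L,
                         days_per_year = 20L, grid_resolution = 100) {
  region_spec(x_extent = c(0, 200), y_extent = c(0, 200),
              n_stations = n_stations, n_years = n_years,
              days_per_year = days_per_year,
              grid_resolution = grid_resolution)
}

# network + covariates + ozone in one call
small_sim <- function(seed = 1L, region = small_region(), ...) {
  net <- gen_network(region, seed)
  covs <- gen_covariates(net, region, seed + 1L)
  sim <- gen_o3(covs, net, seed = seed + 2L, ...)
  list(region = region, stations = net, covariates = covs,
       hard = sim$hard, truth = sim$truth)
}

# a tiny hand-made hard-data table (no randomness)
toy_hard <- function() {
  data.frame(station = rep(c("A", "B", "C"), each = 4),
             x = rep(c(0, 30, 60), each = 4),
             y = rep(c(0, 40, 10), each = 4),
             day = rep(1:4, 3),
             o3_ppb = c(30, 32, 31, 29, 40, 41, 39, 42, 25, 24, 26, 27),
             stringsAsFactors = FALSE)
}

reference_coefficients <- function() default_lur_coefficients()$coefficients
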