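# Linear-spline mixed-effects LUR: bases, design, fitting, prediction,
# effect sizes and soft-data construction.

test_that("spline_basis splits values around the knot", {
  cases <- list(list(v = 25, k = 18, low = 18, high = 7),
                list(v = 10, k = 18, low = 10, high = 0),
                list(v = 18, k = 18, low = 18, high = 0))
  for (cs in cases) {
    b <- spline_basis(cs$v, cs$k)
    expect_equal(unname(b[, "low"]), cs$low)
    expect_equal(unname(b[, "high"]), cs$high)
  }
  # low + high reconstructs the value for non-negative inputs
  v <- seq(0, 40, by = 0.7)
  b <- spline_basis(v, 18)
  expect_equal(rowSums(b), v)
})

test_that("build_design expands covariates, drops incomplete rows", {
  reg <- small_region(n_stations = 3L, days_per_year = 4L)
  net <- gen_network(reg, 1)
  covs <- gen_covariates(net, reg, 2)
  des <- build_design(covs, net)
  expect_equal(nrow(des), 12L)
  expect_equal(attr(des, "dropped"), 0L)
  expect_identical(names(des)[-(1:4)],
                   c("const", "temp_low", "temp_high", "precipitation",
                     "doy", "year", "road_low", "road_high", "lat_low",
                     "lat_high"))
  # one missing temperature drops exactly one row
  covs2 <- covs
  covs2$temperature[5] <- NA
  des2 <- build_design(covs2, net)
  expect_equal(nrow(des2), 11L)
  expect_equal(attr(des2, "dropped"), 1L)
  # unknown station id is a referential-integrity error
  covs3 <- covs
  covs3$station[1] <- "NOPE"
  expect_error(build_design(covs3, net), "unknown station")
})

test_that("a fully crossed seasonal design has 152 x 20 x 39 rows", {
  reg <- region_spec(n_stations = 39L, n_years = 20L,
                     days_per_year = 152L)
  net <- gen_network(reg, 3)
  covs <- gen_covariates(net, reg, 4)
  des <- build_design(covs, net)
  expect_equal(nrow(des), 118560L)
})

test_that("predict_fixed is the inner product with the coefficients", {
  beta <- reference_coefficients()
  # all covariates at their zero reference: the constant
  d0 <- data.frame(const = 1, temp_low = 0, temp_high = 0,
                   precipitation = 0, doy = 0, year = 0, road_low = 0,
                   road_high = 0, lat_low = 0, lat_high = 0)
  expect_equal(predict_fixed(beta, d0), 39.530)
  # hand-computed combination at temperature 25, day 60, year 15,
  # road 5, latitude 100
  d1 <- data.frame(const = 1, temp_low = 18, temp_high = 7,
                   precipitation = 0, doy = 60, year = 15, road_low = 5,
                   road_high = 0, lat_low = 50, lat_high = 50)
  expect_equal(predict_fixed(beta, d1), 42.257, tolerance = 1e-10)
  # linearity: prediction of a convex combination of rows equals the
  # combination of the predictions
  lam <- 0.3
  dm <- d0 * lam + d1 * (1 - lam)
  expect_equal(predict_fixed(beta, dm),
               lam * predict_fixed(beta, d0) +
                 (1 - lam) * predict_fixed(beta, d1))
  d_na <- d1; d_na$doy <- NA
  expect_error(predict_fixed(beta, d_na), "missing covariate")
})

test_that("effect sizes reproduce the reference coefficient table", {
  beta <- reference_coefficients()
  expect_equal(effect_size(beta, "precipitation", 0, 123.8), -1.238,
               tolerance = 1e-9)
  expect_equal(effect_size(beta, "road_density", 0, 25.4, knot = 15),
               -14.995, tolerance = 5e-4)
  expect_equal(abs(effect_size(beta, "doy", 0, 153)), 16.371,
               tolerance = 1e-9)
  expect_error(effect_size(beta, "road_density", 16, 25.4, knot = 15),
               "knot")
  expect_error(effect_size(beta, "precipitation", 0, 10, knot = 5),
               "not splined")
})

test_that("fit_lur recovers generating coefficients without noise and is
           deterministic", {
  reg <- small_region(n_stations = 15L, n_years = 2L,
                      days_per_year = 15L)
  net <- gen_network(reg, 7)
  covs <- gen_covariates(net, reg, 8)
  sim <- gen_o3(covs, net, intercept_sd = 0, resid_sd = 0, seed = 9)
  des <- build_design(covs, net)
  fit <- fit_lur(des, sim$hard$o3_ppb)
  expect_equal(unclass(fit$coefficients),
               unclass(reference_coefficients()), tolerance = 1e-6)
  expect_equal(fit$sigma_u, 0)
  # with noise: REML fit is deterministic given the data
  sim2 <- gen_o3(covs, net, seed = 10)
  f1 <- fit_lur(des, sim2$hard$o3_ppb)
  f2 <- fit_lur(des, sim2$hard$o3_ppb)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_true(all(eigen(f1$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_equal(f1$se, sqrt(diag(f1$vcov)))
})

test_that("fit_lur names collinear columns in singular designs", {
  reg <- small_region(n_stations = 5L, days_per_year = 10L)
  net <- gen_network(reg, 11)
  covs <- gen_covariates(net, reg, 12)
  des <- build_design(covs, net)   # single year: year column is constant 0
  expect_error(fit_lur(des, rnorm(nrow(des), 30, 5)), "year")
})

test_that("predict_error_sd propagates the coefficient covariance", {
  reg <- small_region(n_stations = 6L, n_years = 2L, days_per_year = 20L)
  net <- gen_network(reg, 13)
  covs <- gen_covariates(net, reg, 14)
  sim <- gen_o3(covs, net, seed = 15)
  des <- build_design(covs, net)
  fit <- fit_lur(des, sim$hard$o3_ppb)
  rows <- des[1:5, ]
  sd_q <- predict_error_sd(fit, rows)
  # strictly larger than the random-intercept floor
  expect_true(all(sd_q > fit$sigma_u))
  # brute-force sampling oracle: SD of fixed predictions over draws of
  # the coefficients from N(beta, Sigma), plus sigma_u^2
  X <- as.matrix(rows[names(fit$coefficients)])
  set.seed(99)
  L <- t(chol(fit$vcov + diag(1e-12, 10)))
  draws <- matrix(rnorm(10 * 20000), 10)
  pr <- X %*% (unclass(fit$coefficients) + L %*% draws)
  mc <- sqrt(apply(pr, 1, var) + fit$sigma_u^2)
  expect_equal(sd_q, unname(mc), tolerance = 0.03)
  # degenerate covariance: the error is exactly sigma_u
  fit0 <- fit
  fit0$vcov <- matrix(0, 10, 10, dimnames = dimnames(fit$vcov))
  fit0$se[] <- 0
  expect_equal(predict_error_sd(fit0, rows),
               rep(fit$sigma_u, nrow(rows)))
  # the literal variant ignores the design row
  sd_l <- predict_error_sd(fit, rows, method = "literal")
  expect_equal(stats::var(sd_l), 0)
})

test_that("make_soft_data skips incomplete grid-days and counts them", {
  reg <- small_region(n_stations = 12L, n_years = 2L,
                      days_per_year = 10L, grid_resolution = 70)
  net <- gen_network(reg, 16)
  covs <- gen_covariates(net, reg, 17)
  sim <- gen_o3(covs, net, seed = 18)
  des <- build_design(covs, net)
  fit <- fit_lur(des, sim$hard$o3_ppb)
  grid <- gen_grid_covariates(reg, net, covs, 19,
                              days = reg$dates[1:5])
  soft <- make_soft_data(fit, grid)
  expect_equal(nrow(soft) + attr(soft, "skipped"), nrow(grid))
  expect_true(all(is.finite(soft$sd_ppb)) && all(soft$sd_ppb > 0))
  # knock out one precipitation value: one more skip
  grid2 <- grid
  grid2$precipitation[3] <- NA
  soft2 <- make_soft_data(fit, grid2)
  expect_equal(attr(soft2, "skipped"), attr(soft, "skipped") + 1L)
  expect_equal(nrow(soft2), nrow(soft) - 1L)
  # empty result warns rather than failing silently
  grid3 <- grid
  grid3$temperature <- NA
  expect_warning(make_soft_data(fit, grid3), "empty")
})
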