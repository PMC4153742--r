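# Estimation engine: neighbor selection, the analytic Gaussian solver,
# the quadrature oracle and the full estimation pipeline.

test_that("neighbor selection ranks by covariance with deterministic
           tie-breaks", {
  m <- quebec_o3_covariance()
  cfg <- neighborhood_config(max_hard = 10, max_soft = 10,
                             spatial_radius = 100, temporal_radius = 10)
  pt <- list(x = 0, y = 0, day = 5)
  # coincident datum ranks first
  hz <- data.frame(station = c("A", "B", "C"), x = c(0, 10, 50),
                   y = c(0, 0, 0), day = c(5, 5, 5), z = 1:3)
  nb <- select_neighbors(pt, hz, NULL, cfg, m)
  expect_equal(nb$hard[1], 1L)
  # all data outside the radii: empty selections
  far <- data.frame(station = "A", x = 1000, y = 1000, day = 5, z = 1)
  expect_length(select_neighbors(pt, far, NULL, cfg, m)$hard, 0)
  # 20 equidistant same-day data, max 10: selection of exactly 10,
  # stable under permutation of the input rows
  ang <- seq(0, 2 * pi, length.out = 21)[-21]
  eq <- data.frame(station = sprintf("S%02d", 1:20),
                   x = 30 * cos(ang), y = 30 * sin(ang), day = 5,
                   z = rnorm(20))
  nb1 <- select_neighbors(pt, eq, NULL, cfg, m)
  expect_length(nb1$hard, 10)
  p <- c(7:20, 1:6)
  nb2 <- select_neighbors(pt, eq[p, ], NULL, cfg, m)
  expect_identical(eq$station[nb1$hard], eq[p, ]$station[nb2$hard])
})

test_that("solve_gaussian matches closed forms and limits", {
  m <- quebec_o3_covariance()
  pt <- list(x = 0, y = 0, day = 0)
  none <- data.frame(x = numeric(0), y = numeric(0), day = numeric(0),
                     z = numeric(0))
  # hard datum at zero lag: exact interpolation, zero variance
  h <- data.frame(x = 0, y = 0, day = 0, z = 1.7)
  s0 <- solve_gaussian(pt, h, NULL, m)
  expect_equal(s0$mean, 1.7)
  expect_equal(s0$var, 0)
  # single soft neighbor at zero lag, sill 1: mean mu/(1+v)
  soft <- data.frame(x = 0, y = 0, day = 0, mean_z = 0.8, var_z = 0.5)
  s1 <- solve_gaussian(pt, none, soft, m)
  expect_equal(s1$mean, 0.8 / 1.5, tolerance = 1e-9)
  expect_equal(s1$var, 1 - 1 / 1.5, tolerance = 1e-9)
  # uninformative soft data recover the hard-only solution
  h2 <- data.frame(x = c(10, 40), y = c(0, 10), day = c(1, 0),
                   z = c(0.5, -0.2))
  s_hard <- solve_gaussian(pt, h2, NULL, m)
  soft_inf <- data.frame(x = 5, y = 5, day = 0, mean_z = 3,
                         var_z = 1e12)
  s_both <- solve_gaussian(pt, h2, soft_inf, m)
  expect_equal(s_both$mean, s_hard$mean, tolerance = 1e-6)
  expect_equal(s_both$var, s_hard$var, tolerance = 1e-6)
})

test_that("posterior variance is bounded by the sill and shrinks as
           data are added", {
  m <- quebec_o3_covariance()
  set.seed(20)
  for (k in 1:25) {
    pt <- list(x = runif(1, 0, 100), y = runif(1, 0, 100),
               day = sample(0:10, 1))
    nh <- sample(1:6, 1)
    h <- data.frame(x = runif(nh, 0, 100), y = runif(nh, 0, 100),
                    day = sample(0:10, nh, TRUE), z = rnorm(nh))
    s_few <- solve_gaussian(pt, h[1, , drop = FALSE], NULL, m)
    s_all <- solve_gaussian(pt, h, NULL, m)
    expect_lte(s_all$var, model_covariance(m, 0, 0) + 1e-12)
    expect_lte(s_all$var, s_few$var + 1e-9)
    expect_gte(s_all$var, 0)
  }
})

test_that("the analytic solution equals the quadrature oracle", {
  m <- quebec_o3_covariance()
  set.seed(21)
  worst <- 0
  for (k in 1:50) {
    nh <- sample(0:5, 1)
    ns <- sample(0:3, 1)
    if (nh + ns == 0) nh <- 1
    h <- data.frame(x = runif(nh, 0, 120), y = runif(nh, 0, 120),
                    day = sample(0:8, nh, TRUE), z = rnorm(nh))
    s <- data.frame(x = runif(ns, 0, 120), y = runif(ns, 0, 120),
                    day = sample(0:8, ns, TRUE), mean_z = rnorm(ns),
                    var_z = runif(ns, 0.05, 2))
    pt <- list(x = runif(1, 0, 120), y = runif(1, 0, 120),
               day = sample(0:8, 1))
    a <- solve_gaussian(pt, h, s, m)
    b <- bme_numeric_oracle(pt, h, s, m)
    worst <- max(worst, abs(a$mean - b$mean), abs(a$var - b$var))
  }
  expect_lt(worst, 1e-6)
})

test_that("zero soft error variance acts like hard data in the oracle", {
  m <- quebec_o3_covariance()
  pt <- list(x = 5, y = 5, day = 2)
  h <- data.frame(x = 20, y = 0, day = 1, z = 0.6)
  s <- data.frame(x = 0, y = 0, day = 2, mean_z = 1.1, var_z = 0)
  as_hard <- solve_gaussian(pt, rbind(h, data.frame(x = 0, y = 0,
                                                    day = 2, z = 1.1)),
                            NULL, m)
  orc <- bme_numeric_oracle(pt, h, s, m)
  expect_equal(orc$mean, as_hard$mean, tolerance = 1e-6)
  expect_equal(orc$var, as_hard$var, tolerance = 1e-6)
})

test_that("estimate_points reproduces observations at data points and
           flags empty neighborhoods", {
  s <- small_sim(seed = 51)
  m <- quebec_o3_covariance()
  tr <- fit_transform(s$hard)
  targets <- s$hard[c(3, 17, 44), c("x", "y", "day")]
  est <- estimate_points(targets, s$hard, NULL, m, tr,
                         mode = "kriging")
  expect_equal(est$mean_ppb, s$hard$o3_ppb[c(3, 17, 44)],
               tolerance = 1e-8)
  expect_equal(est$sd_ppb, rep(0, 3), tolerance = 1e-6)
  expect_true(all(est$status == "ok"))
  # a target out of reach of every datum
  far <- data.frame(x = 5000, y = 5000, day = 1000)
  est2 <- estimate_points(far, s$hard, NULL, m, tr, mode = "kriging")
  expect_equal(est2$status, "no-neighbors")
  expect_true(is.na(est2$mean_ppb))
})

test_that("kriging mode ignores the soft table entirely", {
  s <- small_sim(seed = 52)
  m <- quebec_o3_covariance()
  tr <- fit_transform(s$hard)
  targets <- data.frame(x = c(40, 90), y = c(40, 120), day = c(3, 8))
  soft_a <- data.frame(x = 50, y = 50, day = 3, mean_ppb = 80,
                       sd_ppb = 1)
  e0 <- estimate_points(targets, s$hard, NULL, m, tr, mode = "kriging")
  e1 <- estimate_points(targets, s$hard, soft_a, m, tr,
                        mode = "kriging")
  expect_identical(e0$mean_ppb, e1$mean_ppb)
  # while bme mode uses it
  e2 <- estimate_points(targets, s$hard, soft_a, m, tr, mode = "bme")
  expect_false(isTRUE(all.equal(e0$mean_ppb, e2$mean_ppb)))
  expect_equal(e2$n_soft[1], 1L)
})

test_that("estimates are invariant to permuting the input data order", {
  s <- small_sim(seed = 53)
  m <- quebec_o3_covariance()
  tr <- fit_transform(s$hard)
  targets <- data.frame(x = c(60, 100), y = c(30, 140), day = c(4, 9))
  set.seed(22)
  p <- sample(nrow(s$hard))
  e1 <- estimate_points(targets, s$hard, NULL, m, tr, mode = "kriging")
  e2 <- estimate_points(targets, s$hard[p, ], NULL, m,
                        fit_transform(s$hard[p, ]), mode = "kriging")
  expect_equal(e1$mean_ppb, e2$mean_ppb, tolerance = 1e-9)
})

test_that("hard data far outside the soft envelope are flagged as the
           estimation-failure mode", {
  s <- small_sim(seed = 54)
  m <- quebec_o3_covariance()
  tr <- fit_transform(s$hard)
  # soft records claiming a very low, precise range at the target
  target <- s$hard[10, c("x", "y", "day")]
  soft <- data.frame(x = target$x + 1, y = target$y, day = target$day,
                     mean_ppb = 1, sd_ppb = 0.01)
  est <- estimate_points(target, s$hard, soft, m, tr, mode = "bme",
                         soft_conflict_sd = 4)
  expect_equal(est$status, "numerical-failure")
  # disabled check estimates normally
  est2 <- estimate_points(target, s$hard, soft, m, tr, mode = "bme")
  expect_equal(est2$status, "ok")
})
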