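# Cross-validation protocol and agreement metrics.

test_that("rmse and r2 behave on hand-made cases", {
  obs <- c(30, 35, 40, 28)
  expect_equal(as.numeric(rmse(obs, obs)), 0)
  expect_equal(as.numeric(r2(obs, obs)), 1)
  expect_equal(as.numeric(rmse(c(10, 10), c(11, 9))), 1)
  # missing estimates are excluded and counted
  est <- c(31, NA, 41, 29)
  expect_equal(attr(rmse(obs, est), "n_excluded"), 1L)
  expect_error(r2(c(1, 1, 1), c(2, 3, 4)), "zero variance")
  # Monte-Carlo: rmse estimates the error SD
  set.seed(30)
  o <- rnorm(10000, 30, 10)
  e <- o + rnorm(10000, 0, 3)
  expect_equal(as.numeric(rmse(o, e)), 3, tolerance = 0.03 * 3)
  expect_true(as.numeric(r2(o, e)) >= 0 && as.numeric(r2(o, e)) <= 1)
})

test_that("pcmse matches the published worked example", {
  expect_equal(pcmse(9.164, 7.057), -23.0, tolerance = 0.05)
  expect_equal(round(pcmse(8.747, 7.057), 1), -19.3)
  expect_equal(pcmse(5, 5), 0)
  # monotone decreasing in the model RMSE
  v <- vapply(seq(6, 12, by = 0.5), pcmse, numeric(1),
              rmse_reference = 7.057)
  expect_true(all(diff(v) < 0))
  # the mse-ratio variant
  expect_equal(pcmse(10, 5, type = "mse"), 100 * (25 - 100) / 100)
  expect_error(pcmse(0, 5), "positive")
})

test_that("kappa on exceedances matches direct 2x2 computations", {
  # TP = 40, FN = 10, FP = 10, TN = 40 -> po = 0.8, pe = 0.5, kappa 0.6
  obs <- c(rep(70, 50), rep(60, 50))
  est <- c(rep(70, 40), rep(60, 10), rep(70, 10), rep(60, 40))
  k <- kappa_exceedance(obs, est, 65)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$n_observed_exceed, 50)
  expect_true(k$ci[1] < 0.6 && k$ci[2] > 0.6)
  # perfect agreement with both classes present
  kp <- kappa_exceedance(obs, obs, 65)
  expect_equal(kp$kappa, 1)
  # independent binarizations are near zero
  set.seed(31)
  o <- ifelse(runif(10000) < 0.3, 70, 60)
  e <- ifelse(runif(10000) < 0.3, 70, 60)
  expect_lt(abs(kappa_exceedance(o, e, 65)$kappa), 0.05)
  # label swap invariance: mirror both series around the threshold
  k2 <- kappa_exceedance(130 - o, 130 - e, 65)
  expect_equal(k2$kappa, kappa_exceedance(o, e, 65)$kappa,
               tolerance = 1e-12)
  # degenerate margins raise a typed error
  expect_error(kappa_exceedance(rep(60, 5), rep(60, 5), 65),
               class = "bmelur_kappa_undefined")
})

test_that("error summaries group means and rmses correctly", {
  rec <- structure(data.frame(station = c("A", "A", "B"),
                              day = c(1, 2, 1), observed = c(30, 32, 40),
                              est_bme = c(31, 31, 44),
                              status_bme = "ok",
                              stringsAsFactors = FALSE),
                   class = c("cv_records", "data.frame"))
  es <- error_summaries(rec, "bme")
  expect_equal(es$by_station$mean_error, c(0, 4),
               ignore_attr = TRUE)
  expect_equal(es$by_station$rmse[2], 4, ignore_attr = TRUE)
  expect_equal(es$by_day$n, c(2, 1), ignore_attr = TRUE)
  # all-zero errors give all-zero summaries
  rec0 <- rec; rec0$est_bme <- rec0$observed
  es0 <- error_summaries(rec0, "bme")
  expect_true(all(es0$by_station$mean_error == 0) &&
                all(es0$by_day$rmse == 0))
})

test_that("window-0 cross-validation reproduces retained observations
           (leak control) and window > 0 audits exclusion", {
  s <- small_sim(seed = 61,
                 region = small_region(n_stations = 8L,
                                       days_per_year = 15L))
  m <- quebec_o3_covariance()
  tr <- fit_transform(s$hard)
  cfg0 <- cv_config(exclusion_window = 0, models = "kriging",
                    max_eval = 10)
  rec0 <- loso_cv(s$hard, NULL, m, tr, config = cfg0)
  expect_equal(rec0$est_kriging, rec0$observed, tolerance = 1e-8)
  cfg1 <- cv_config(exclusion_window = 365,
                    models = c("kriging", "bme"), max_eval = 10)
  soft <- data.frame(x = s$hard$x, y = s$hard$y, day = s$hard$day,
                     mean_ppb = mean(s$hard$o3_ppb), sd_ppb = 10)
  rec1 <- loso_cv(s$hard, soft, m, tr, config = cfg1)
  expect_true(all(rec1$audit_ok))
  expect_false(isTRUE(all.equal(rec1$est_kriging, rec1$observed)))
  expect_true(all(rec1$status_kriging %in%
                    c("ok", "no-neighbors", "numerical-failure")))
})

test_that("the LUR column carries fixed-effect predictions", {
  s <- small_sim(seed = 62,
                 region = small_region(n_stations = 6L, n_years = 2L,
                                       days_per_year = 10L))
  m <- quebec_o3_covariance()
  des <- build_design(s$covariates, s$stations)
  fit <- fit_lur(des, s$hard$o3_ppb)
  lp <- data.frame(station = des$station, day = des$day,
                   pred = predict_fixed(fit, des))
  cfg <- cv_config(models = c("lur", "kriging"), max_eval = 8)
  rec <- loso_cv(s$hard, NULL, m, NULL, lur_pred = lp, config = cfg)
  key <- match(paste(rec$station, rec$day), paste(lp$station, lp$day))
  expect_equal(rec$est_lur, lp$pred[key])
})

test_that("cv_metrics summarizes models and computes pcmse against the
           reference", {
  rec <- structure(data.frame(
    station = rep(c("A", "B"), each = 10), day = rep(1:10, 2),
    observed = c(seq(20, 56, by = 4), seq(30, 66, by = 4)),
    stringsAsFactors = FALSE), class = c("cv_records", "data.frame"))
  set.seed(32)
  rec$est_bme <- rec$observed + rnorm(20, 0, 2)
  rec$est_kriging <- rec$observed + rnorm(20, 0, 6)
  rec$est_lur <- rec$observed + rnorm(20, 0, 4)
  rec$status_bme <- "ok"
  rec$status_kriging <- c(rep("ok", 19), "numerical-failure")
  met <- cv_metrics(rec, threshold = 45)
  expect_setequal(met$model, c("lur", "kriging", "bme"))
  expect_equal(met$n[met$model == "kriging"], 19)
  expect_equal(met$n_excluded[met$model == "kriging"], 1)
  expect_true(is.na(met$pcmse[met$model == "bme"]))
  kr <- met[met$model == "kriging", ]
  expect_equal(kr$pcmse,
               pcmse(kr$rmse, met$rmse[met$model == "bme"]))
  expect_true(all(met$r2 >= 0 & met$r2 <= 1))
})
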