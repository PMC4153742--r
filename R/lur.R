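#' @name lur
#' @title Linear-spline mixed-effects land-use regression for ozone
#'
#' @description
#' The LUR models daily 8-hr summer ozone (ppb) at monitoring stations as a
#' linear function of ten fixed terms plus a per-station random intercept:
#' a constant; linear splines in 8-hr mean temperature (knot 18 degC), road
#' density (knot 15 km/pi-km2) and rescaled latitude (knot 50 km), giving a
#' separate slope below and above each knot; and linear terms in daily
#' precipitation (mm), rescaled day of year (numeric day minus 121) and
#' rescaled year (year minus 1990).  The fixed-effect part of the fitted
#' model supplies "soft data" -- a Gaussian predictive distribution at
#' unmonitored grid cells -- for the BME-LUR estimator.
#'
#' The fixed design columns are frozen in the order
#' `const, temp_low, temp_high, precipitation, doy, year, road_low,
#' road_high, lat_low, lat_high` so that coefficient files are portable.
NULL

# Frozen fixed-effect term order.
lur_terms <- c("const", "temp_low", "temp_high", "precipitation", "doy",
               "year", "road_low", "road_high", "lat_low", "lat_high")

#' Default spline knots for the ozone LUR
#'
#' One interior knot per splined covariate: 18 degC for 8-hr temperature,
#' 15 km/pi-km2 for road density and 50 km for rescaled latitude.
#'
#' @return Named numeric vector of knot locations.
#' @export
default_knots <- function() {
  c(temperature = 18, road_density = 15, latitude = 50)
}

#' Linear-spline basis with a single knot
#'
#' Splits a covariate value into its below-knot and above-knot linear
#' segments: `low = min(value, knot)`, `high = max(value - knot, 0)`, so
#' that `low + high = value` whenever `value >= 0`.
#'
#' @param value Numeric vector of covariate values.
#' @param knot Single numeric knot location.
#' @return Two-column matrix with columns `low` and `high`.
#' @examples
#' spline_basis(25, 18)   # 18 and 7
#' spline_basis(10, 18)   # 10 and 0
#' @export
spline_basis <- function(value, knot) {
  if (!all(is.finite(value)) || !is.finite(knot))
    stop("spline_basis() requires finite inputs", call. = FALSE)
  cbind(low = pmin(value, knot), high = pmax(value - knot, 0))
}

#' Construct a validated 10-term LUR coefficient vector
#'
#' @param x Numeric vector of length 10, optionally named with the frozen
#'   term names (see [lur]); unnamed vectors are assumed to be in that
#'   order.
#' @return Named numeric vector of class `lur_coefficients`.
#' @export
lur_coefficients <- function(x) {
  x <- unlist(x)
  if (length(x) != 10L || !is.numeric(x) || anyNA(x))
    stop("LUR coefficients must be 10 finite numbers (terms: ",
         paste(lur_terms, collapse = ", "), ")", call. = FALSE)
  if (is.null(names(x))) names(x) <- lur_terms
  if (!setequal(names(x), lur_terms))
    stop("coefficient names must be: ", paste(lur_terms, collapse = ", "),
         call. = FALSE)
  structure(x[lur_terms], class = "lur_coefficients")
}

#' Packaged reference coefficients for the Quebec summer ozone LUR
#'
#' Reads the coefficient file shipped with the package
#' (`extdata/lur_quebec_defaults.csv`): the published fixed-effect
#' estimates and standard errors for the 1990--2009 Quebec summer ozone
#' network, with random-intercept SD 2.464 ppb and residual SD 8.904 ppb.
#' These are the default generating values for the synthetic-data module
#' and the default LUR when no fit is supplied.
#'
#' @return A list with elements `coefficients` ([lur_coefficients]), `se`
#'   (named numeric), `sigma_u` and `sigma_e` (ppb).
#' @export
default_lur_coefficients <- function() {
  path <- system.file("extdata", "lur_quebec_defaults.csv",
                      package = "bmelur", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  est <- setNames(tab$estimate, tab$term)
  list(coefficients = lur_coefficients(est[lur_terms]),
       se = setNames(tab$se, tab$term)[lur_terms],
       sigma_u = unname(est["sigma_u"]),
       sigma_e = unname(est["sigma_e"]))
}

#' Build the fixed-effect design table for the ozone LUR
#'
#' Joins station-day covariates to station attributes and expands them into
#' the ten frozen design columns (constant, temperature spline pair,
#' precipitation, day of year, year, road-density spline pair, latitude
#' spline pair).  Rows with any missing covariate are dropped; the number
#' dropped is recorded in the `"dropped"` attribute.
#'
#' @param covariates Data frame with columns `station`, `day`, `doy`,
#'   `year`, `temperature`, `precipitation`.
#' @param stations Data frame with columns `station`, `x`, `y`,
#'   `road_density`, `latitude`.
#' @param knots Named knots as from [default_knots()].
#' @return Data frame of class `lur_design` with identifier columns
#'   (`station`, `day`, `x`, `y`) and the ten design columns; attributes
#'   `dropped` (row count) and `knots`.
#' @export
build_design <- function(covariates, stations, knots = default_knots()) {
  need_cov <- c("station", "day", "doy", "year", "temperature",
                "precipitation")
  need_sta <- c("station", "x", "y", "road_density", "latitude")
  miss <- setdiff(need_cov, names(covariates))
  if (length(miss))
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(need_sta, names(stations))
  if (length(miss))
    stop("station table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(covariates$station, stations$station)
  if (length(unknown))
    stop("covariates reference unknown station id(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  m <- merge(covariates[need_cov], stations[need_sta], by = "station",
             sort = FALSE)
  m <- m[order(m$station, m$day), , drop = FALSE]
  vars <- c("temperature", "precipitation", "doy", "year", "road_density",
            "latitude")
  ok <- stats::complete.cases(m[vars])
  dropped <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  tb <- spline_basis(m$temperature, knots[["temperature"]])
  rb <- spline_basis(m$road_density, knots[["road_density"]])
  lb <- spline_basis(m$latitude, knots[["latitude"]])
  out <- data.frame(station = m$station, day = m$day, x = m$x, y = m$y,
                    const = 1, temp_low = tb[, 1], temp_high = tb[, 2],
                    precipitation = m$precipitation, doy = m$doy,
                    year = m$year, road_low = rb[, 1], road_high = rb[, 2],
                    lat_low = lb[, 1], lat_high = lb[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dropped") <- dropped
  attr(out, "knots") <- knots
  class(out) <- c("lur_design", "data.frame")
  out
}

# The 10-column fixed-effect matrix of a design table.
design_matrix <- function(design) {
  as.matrix(design[lur_terms])
}

#' Fit the mixed-effects LUR
#'
#' Fits ozone on the ten fixed design terms with a per-station random
#' intercept by REML (default) or ML through [lme4::lmer()].  The fit is
#' deterministic given the data.  When the data are exactly linear in the
#' design (residual variation numerically zero) the degenerate fit is
#' returned from ordinary least squares with zero variance components.
#'
#' @param design A `lur_design` from [build_design()].
#' @param o3 Numeric ozone observations (ppb), one per design row.
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `lur_fit`: `coefficients`, `vcov` (10x10
#'   fixed-effects covariance), `se`, `sigma_u` (random-intercept SD,
#'   ppb), `sigma_e` (residual SD, ppb), `ranef` (estimated station
#'   intercepts), `n`, `knots`.
#' @export
fit_lur <- function(design, o3, method = c("REML", "ML")) {
  method <- match.arg(method)
  if (length(o3) != nrow(design))
    stop("length(o3) must equal nrow(design)", call. = FALSE)
  if (nrow(design) < 20L)
    stop("at least 20 station-days are required to fit the LUR",
         call. = FALSE)
  if (length(unique(design$station)) < 2L)
    stop("at least 2 stations are required (random intercept)",
         call. = FALSE)
  X <- design_matrix(design)
  if (anyNA(X) || anyNA(o3))
    stop("design and o3 must be complete (no missing values)",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  knots <- attr(design, "knots")
  ols <- stats::lm.fit(X, o3)
  if (sqrt(mean(ols$residuals^2)) < 1e-8) {
    # noiseless data: variance components are identically zero
    beta <- lur_coefficients(ols$coefficients[lur_terms])
    st <- sort(unique(design$station))
    return(structure(list(
      coefficients = beta,
      vcov = matrix(0, 10, 10, dimnames = list(lur_terms, lur_terms)),
      se = setNames(numeric(10), lur_terms),
      sigma_u = 0, sigma_e = 0,
      ranef = setNames(numeric(length(st)), st),
      n = nrow(design), knots = knots, method = "OLS-degenerate"),
      class = "lur_fit"))
  }
  d <- data.frame(.o3 = o3, .station = design$station, X,
                  check.names = FALSE)
  form <- stats::as.formula(paste(
    ".o3 ~ 0 +", paste(lur_terms, collapse = " + "), "+ (1 | .station)"))
  fit <- lme4::lmer(form, data = d, REML = (method == "REML"),
                    control = lme4::lmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(fit)[lur_terms]
  V <- as.matrix(stats::vcov(fit))[lur_terms, lur_terms]
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == ".station"][1]
  re <- lme4::ranef(fit)$.station
  structure(list(
    coefficients = lur_coefficients(beta),
    vcov = V,
    se = sqrt(diag(V)),
    sigma_u = sigma_u,
    sigma_e = stats::sigma(fit),
    ranef = setNames(re[[1]], rownames(re)),
    n = nrow(design), knots = knots, method = method),
    class = "lur_fit")
}

#' @export
print.lur_fit <- function(x, ...) {
  cat("Linear-spline mixed-effects LUR (", x$method, "), n = ", x$n,
      " station-days\n", sep = "")
  print(round(cbind(estimate = unclass(x$coefficients), se = x$se), 4))
  cat("Random-intercept SD: ", round(x$sigma_u, 3),
      " ppb;  residual SD: ", round(x$sigma_e, 3), " ppb\n", sep = "")
  invisible(x)
}

# Accept either a lur_fit, a lur_coefficients vector, or a bare numeric(10).
as_lur_coefficients <- function(object) {
  if (inherits(object, "lur_fit")) object$coefficients
  else lur_coefficients(object)
}

#' Fixed-effect LUR prediction
#'
#' The inner product of the ten fixed coefficients with each design row.
#' Only the fixed portion is used for prediction at unmonitored locations
#' because the mean random effect is zero.
#'
#' @param object A `lur_fit`, `lur_coefficients`, or numeric vector of 10
#'   coefficients in the frozen term order.
#' @param design A `lur_design` (or any data frame containing the ten
#'   design columns).
#' @return Numeric vector of predicted ozone (ppb).
#' @export
predict_fixed <- function(object, design) {
  beta <- as_lur_coefficients(object)
  X <- as.matrix(design[, lur_terms, drop = FALSE])
  if (anyNA(X))
    stop("missing covariate value in prediction rows", call. = FALSE)
  drop(X %*% unclass(beta))
}

#' Prediction-error SD of the fixed-effect LUR prediction
#'
#' The soft-data error. The default (`method = "quadratic"`) propagates
#' the full fixed-effects covariance through the design row,
#' `var = x' Sigma x + sigma_u^2`, which accounts for coefficient
#' covariances and the magnitude of the covariates.  `method = "literal"`
#' instead sums the squared coefficient standard errors plus
#' `sigma_u^2`, ignoring the design row; it is provided for comparison
#' with the simpler published description of the soft-data error.
#' Optionally the residual variance `sigma_e^2` is added.
#'
#' @param fit A `lur_fit`.
#' @param design Design rows as in [predict_fixed()].
#' @param method `"quadratic"` (default) or `"literal"`.
#' @param include_residual Add `sigma_e^2` to the error variance?
#' @return Numeric vector of prediction-error SDs (ppb), strictly
#'   positive whenever `sigma_u > 0`.
#' @export
predict_error_sd <- function(fit, design,
                             method = c("quadratic", "literal"),
                             include_residual = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "lur_fit"))
  X <- as.matrix(design[, lur_terms, drop = FALSE])
  if (anyNA(X))
    stop("missing covariate value in prediction rows", call. = FALSE)
  V <- fit$vcov
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(abs(V), 1))
    stop("fixed-effects covariance matrix is not positive semi-definite",
         call. = FALSE)
  v <- if (method == "quadratic") unname(rowSums((X %*% V) * X))
       else rep(sum(fit$se^2), nrow(X))
  v <- pmax(v, 0) + fit$sigma_u^2
  if (include_residual) v <- v + fit$sigma_e^2
  sqrt(v)
}

#' Effect size of a LUR covariate over its observed range
#'
#' For a non-splined variable the effect size is `beta * (v_max - v_min)`.
#' For a splined variable it is
#' `beta_lower * knot - beta_lower * v_min + beta_upper * (v_max - knot)`,
#' i.e. the fitted change in ozone across the variable's full observed
#' range.  Values are reported signed.
#'
#' @param coeffs Coefficients as accepted by [predict_fixed()].
#' @param variable One of `"temperature"`, `"precipitation"`, `"doy"`,
#'   `"year"`, `"road_density"`, `"latitude"`.
#' @param v_min,v_max Observed range of the covariate.
#' @param knot Knot location for splined variables (defaults to
#'   [default_knots()] for the three splined variables; must be `NULL`
#'   for non-splined ones).
#' @return Effect size in ppb.
#' @export
effect_size <- function(coeffs, variable, v_min, v_max, knot = NULL) {
  beta <- as_lur_coefficients(coeffs)
  splined <- list(temperature = c("temp_low", "temp_high"),
                  road_density = c("road_low", "road_high"),
                  latitude = c("lat_low", "lat_high"))
  plain <- c(precipitation = "precipitation", doy = "doy", year = "year")
  if (variable %in% names(splined)) {
    if (is.null(knot)) knot <- default_knots()[[variable]]
    if (knot < v_min || knot > v_max)
      stop("knot ", knot, " outside [v_min, v_max] for ", variable,
           call. = FALSE)
    b <- beta[splined[[variable]]]
    unname(b[1] * knot - b[1] * v_min + b[2] * (v_max - knot))
  } else if (variable %in% names(plain)) {
    if (!is.null(knot))
      stop(variable, " is not splined; `knot` must be NULL", call. = FALSE)
    unname(beta[plain[[variable]]] * (v_max - v_min))
  } else {
    stop("unknown variable: ", variable, call. = FALSE)
  }
}

#' Derive Gaussian soft data from a fitted LUR
#'
#' Evaluates the fixed-effect prediction and its error SD at grid
#' locations (cell centers), producing one Gaussian soft datum per
#' grid-day with complete predictors.  Grid-days with any missing
#' predictor are skipped and counted in the `"skipped"` attribute.
#'
#' @param fit A `lur_fit`.
#' @param grid_covariates Data frame with columns `x`, `y`, `day`, `doy`,
#'   `year`, `temperature`, `precipitation`, `road_density`, `latitude`.
#' @param knots Spline knots (default: those stored in `fit`).
#' @param method,include_residual Passed to [predict_error_sd()].
#' @return Data frame with columns `x`, `y`, `day`, `mean_ppb`, `sd_ppb`;
#'   attribute `skipped`.
#' @export
make_soft_data <- function(fit, grid_covariates, knots = fit$knots,
                           method = c("quadratic", "literal"),
                           include_residual = FALSE) {
  method <- match.arg(method)
  need <- c("x", "y", "day", "doy", "year", "temperature", "precipitation",
            "road_density", "latitude")
  miss <- setdiff(need, names(grid_covariates))
  if (length(miss))
    stop("grid covariate table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(knots)) knots <- default_knots()
  g <- grid_covariates
  vars <- c("temperature", "precipitation", "doy", "year", "road_density",
            "latitude")
  ok <- stats::complete.cases(g[vars])
  skipped <- sum(!ok)
  g <- g[ok, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no grid-day had a complete predictor set; ",
            "soft-data table is empty", call. = FALSE)
    out <- data.frame(x = numeric(0), y = numeric(0), day = integer(0),
                      mean_ppb = numeric(0), sd_ppb = numeric(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  tb <- spline_basis(g$temperature, knots[["temperature"]])
  rb <- spline_basis(g$road_density, knots[["road_density"]])
  lb <- spline_basis(g$latitude, knots[["latitude"]])
  design <- data.frame(const = 1, temp_low = tb[, 1], temp_high = tb[, 2],
                       precipitation = g$precipitation, doy = g$doy,
                       year = g$year, road_low = rb[, 1],
                       road_high = rb[, 2], lat_low = lb[, 1],
                       lat_high = lb[, 2])
  out <- data.frame(x = g$x, y = g$y, day = g$day,
                    mean_ppb = predict_fixed(fit, design),
                    sd_ppb = predict_error_sd(fit, design, method = method,
                                              include_residual =
                                                include_residual),
                    row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}
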