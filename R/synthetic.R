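#' @name synthetic_data
#' @title Synthetic monitoring networks, covariates and ozone fields
#'
#' @description
#' Generators that emulate the statistical structure of a sparse
#' Quebec-like summer ozone monitoring network: a station network
#' clustered toward the urban south, right-skewed road densities, a
#' seasonal temperature field with a north--south gradient, zero-inflated
#' precipitation, and ozone observations built from the LUR mean
#' structure plus a station random intercept and a residual field drawn
#' from the nested space-time covariance model.  Every generator is
#' deterministic given its seed.  All coordinates are planar km; time is
#' an integer day index with summer seasons of consecutive days separated
#' by 365-day years (daily values are 8-hr means, one per station-day).
NULL

#' Define the simulation region and season calendar
#'
#' @param x_extent,y_extent Planar extents in km (length-2, increasing).
#'   The defaults emulate a region of a few hundred km on each side with
#'   rescaled latitude spanning roughly 0--583 km.
#' @param n_stations Number of monitoring stations (>= 2).
#' @param n_years Number of summer seasons.
#' @param days_per_year Days per season (the May--September 8-hr ozone
#'   season has 152).
#' @param grid_resolution Spacing (km) of the soft-data grid.
#' @return Object of class `region_spec` with a `calendar` data frame
#'   (`day` = absolute day index, `doy` = rescaled day of year 0-based,
#'   `year` = rescaled year index) and `dates`, the ordered day indices.
#' @export
region_spec <- function(x_extent = c(0, 400), y_extent = c(0, 580),
                        n_stations = 30L, n_years = 1L,
                        days_per_year = 152L, grid_resolution = 50) {
  if (length(x_extent) != 2L || length(y_extent) != 2L ||
      diff(x_extent) <= 0 || diff(y_extent) <= 0)
    stop("extents must be increasing length-2 vectors", call. = FALSE)
  if (n_stations < 2L)
    stop("n_stations must be at least 2", call. = FALSE)
  if (n_years < 1L || days_per_year < 1L)
    stop("n_years and days_per_year must be positive", call. = FALSE)
  if (grid_resolution <= 0)
    stop("grid_resolution must be positive", call. = FALSE)
  cal <- do.call(rbind, lapply(seq_len(n_years) - 1L, function(yr) {
    doy <- seq_len(days_per_year) - 1L
    data.frame(day = yr * 365L + 121L + doy, doy = doy, year = yr)
  }))
  structure(list(x_extent = x_extent, y_extent = y_extent,
                 n_stations = as.integer(n_stations),
                 n_years = as.integer(n_years),
                 days_per_year = as.integer(days_per_year),
                 grid_resolution = grid_resolution,
                 calendar = cal, dates = cal$day),
            class = "region_spec")
}

# Right-skewed road-density surface shared by stations and grid cells:
# density decays with distance from the urban center and carries
# multiplicative lognormal noise, truncated to [0, 25.4] km/pi-km2.
# Uses the current RNG stream (call inside with_seed()).
road_density_field <- function(x, y, region) {
  cx <- region$x_extent[1] + 0.2 * diff(region$x_extent)
  cy <- region$y_extent[1] + 0.12 * diff(region$y_extent)
  dc <- sqrt((x - cx)^2 + (y - cy)^2)
  base <- 16 * exp(-dc / 80) + 0.3
  pmin(pmax(base * rlnorm(length(x), meanlog = -0.35, sdlog = 1.1), 0),
       25.4)
}

#' Generate a clustered monitoring network
#'
#' Places `n_stations` stations in the region with a configurable
#' fraction clustered near the southwest corner (emulating the urban
#' south of the study region); the rest are uniform over the region.
#' Road density is drawn from a right-skewed lognormal truncated to
#' [0, 25.4] km/pi-km2, higher inside the cluster; rescaled latitude is
#' `y - min(y)`.
#'
#' @param region A `region_spec`.
#' @param seed Integer seed; identical inputs and seed reproduce the
#'   table exactly.
#' @param cluster_frac Expected fraction of stations in the urban
#'   cluster.
#' @param cluster_sd_frac Cluster spread as a fraction of each extent.
#' @return Data frame with columns `station`, `x`, `y`, `road_density`,
#'   `latitude`.
#' @export
gen_network <- function(region, seed, cluster_frac = 0.6,
                        cluster_sd_frac = 0.12) {
  stopifnot(inherits(region, "region_spec"))
  n <- region$n_stations
  if (n < 2L) stop("n_stations must be at least 2", call. = FALSE)
  xr <- region$x_extent; yr <- region$y_extent
  with_seed(seed, {
    urban <- runif(n) < cluster_frac
    cx <- xr[1] + 0.2 * diff(xr); cy <- yr[1] + 0.12 * diff(yr)
    x <- ifelse(urban, rnorm(n, cx, cluster_sd_frac * diff(xr)),
                runif(n, xr[1], xr[2]))
    y <- ifelse(urban, rnorm(n, cy, cluster_sd_frac * diff(yr)),
                runif(n, yr[1], yr[2]))
    x <- pmin(pmax(x, xr[1]), xr[2])
    y <- pmin(pmax(y, yr[1]), yr[2])
    # avoid exactly coincident stations (degenerate kriging systems)
    while (anyDuplicated(cbind(x, y))) {
      d <- duplicated(cbind(x, y))
      x[d] <- x[d] + runif(sum(d), -0.5, 0.5)
      y[d] <- y[d] + runif(sum(d), -0.5, 0.5)
      x <- pmin(pmax(x, xr[1]), xr[2]); y <- pmin(pmax(y, yr[1]), yr[2])
    }
    road <- road_density_field(x, y, region)
    data.frame(station = sprintf("S%03d", seq_len(n)), x = x, y = y,
               road_density = road, latitude = y - min(y),
               stringsAsFactors = FALSE)
  })
}

#' Generate station-day meteorological covariates
#'
#' Temperature is a seasonal parabola peaking in mid season, minus a
#' north--south gradient, plus a day-level anomaly shared across stations
#' and independent station-day noise (both scaled by `temp_noise_sd`);
#' values are clipped to [-3.5, 33.9] degC.  Precipitation is
#' zero-inflated (about 65% dry days) with gamma-distributed wet-day
#' amounts clipped to [0, 123.8] mm/day.  A missingness rate removes
#' whole station-day records to emulate incomplete coverage.
#'
#' @param stations Station table from [gen_network()].
#' @param region The `region_spec`.
#' @param seed Integer seed.
#' @param missing_rate Probability that a station-day record is missing.
#' @param temp_noise_sd Temperature noise scale (degC); 0 makes
#'   temperature an exact deterministic function of (y, day).
#' @return Data frame with columns `station`, `day`, `doy`, `year`,
#'   `temperature`, `precipitation`.
#' @export
gen_covariates <- function(stations, region, seed, missing_rate = 0,
                           temp_noise_sd = 1.5) {
  stopifnot(inherits(region, "region_spec"))
  if (nrow(stations) == 0L)
    stop("station table must be non-empty", call. = FALSE)
  cal <- region$calendar
  g <- merge(stations[c("station", "y")], cal, by = NULL)
  g <- g[order(g$station, g$day), , drop = FALSE]
  yr <- region$y_extent; dpy <- region$days_per_year
  with_seed(seed, {
    day_anom <- setNames(rnorm(nrow(cal)), cal$day)
    seasonal <- 22 - 10 * ((g$doy - dpy / 2) / (dpy / 2))^2
    gradient <- 10 * (g$y - yr[1]) / diff(yr)
    temp <- seasonal - gradient +
      temp_noise_sd * (1.5 * day_anom[as.character(g$day)] +
                         rnorm(nrow(g)))
    temp <- pmin(pmax(temp, -3.5), 33.9)
    wet <- runif(nrow(g)) < 0.35
    amt <- rgamma(nrow(g), shape = 0.6, scale = 10)
    precip <- pmin(ifelse(wet, amt, 0), 123.8)
    keep <- runif(nrow(g)) >= missing_rate
    data.frame(station = g$station, day = g$day, doy = g$doy,
               year = g$year, temperature = unname(temp),
               precipitation = precip,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  })
}

#' Simulate a zero-mean residual field with nested covariance
#'
#' Draws a station-by-day Gaussian field whose covariance is
#' `resid_sd^2 * model_covariance(model, r, tau)`.  Because the nested
#' model is a sum of two separable components, the field is simulated
#' exactly as the sum of two independent Kronecker-factorized fields:
#' for each component the station-by-station and day-by-day covariance
#' factors are factorized (Cholesky with jitter, eigenvalue fallback for
#' the rank-deficient cosine factor) and applied to an iid normal
#' matrix.  This is exact for the full space-time covariance.
#'
#' @param stations Station table (columns `x`, `y`).
#' @param days Sorted integer day indices.
#' @param model An `stcov_model`.
#' @param resid_sd Marginal residual SD (ppb or n-score units).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Matrix `n_stations x n_days` (dimnames station index / day).
#' @export
sim_resid_field <- function(stations, days, model, resid_sd = 1,
                            seed = NULL) {
  stopifnot(inherits(model, "stcov_model"))
  if (resid_sd < 0) stop("resid_sd must be non-negative", call. = FALSE)
  draw <- function() {
    D <- as.matrix(stats::dist(stations[, c("x", "y")]))
    dt <- abs(outer(days, days, "-"))
    Ls1 <- psd_factor(exp(-3 * D / model$s_range1),
                      "spatial factor, component 1")
    Lt1 <- psd_factor(exp(-3 * dt / model$t_range1),
                      "temporal factor, component 1")
    Ls2 <- psd_factor(exp(-3 * D / model$s_range2),
                      "spatial factor, component 2")
    Lt2 <- psd_factor(cos(pi * dt / model$t_range2),
                      "temporal factor, component 2 (cosine)")
    ns <- nrow(D); nt <- length(days)
    Z <- sqrt(model$w1) *
      (Ls1 %*% matrix(rnorm(ns * nt), ns, nt) %*% t(Lt1)) +
      sqrt(model$w2) *
      (Ls2 %*% matrix(rnorm(ns * nt), ns, nt) %*% t(Lt2))
    dimnames(Z) <- list(NULL, days)
    resid_sd * Z
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate synthetic ozone observations from the LUR generative model
#'
#' Ozone at each station-day is the fixed-effect LUR mean, plus a
#' station intercept drawn from `Normal(0, intercept_sd^2)`, plus a
#' residual from a zero-mean Gaussian field with covariance
#' `resid_sd^2 * model_covariance(resid_model, .)`.  Negative values are
#' truncated to 0 ppb (mirroring the retention of 0-ppb records by
#' early low-sensitivity instruments).
#'
#' @param covariates Covariate table from [gen_covariates()].
#' @param stations Station table from [gen_network()].
#' @param coeffs Generating coefficients (default: the packaged Quebec
#'   reference set).
#' @param intercept_sd Station random-intercept SD (ppb).
#' @param resid_model `stcov_model` for the residual field.
#' @param resid_sd Residual SD (ppb).
#' @param seed Integer seed.
#' @param knots Spline knots.
#' @return List with `hard` (data frame `station`, `x`, `y`, `day`,
#'   `o3_ppb`) and `truth` (class `sim_truth`: generating coefficients,
#'   station intercepts, residual model and SDs, seed, truncation count,
#'   and the residual matrix used).
#' @export
gen_o3 <- function(covariates, stations,
                   coeffs = default_lur_coefficients()$coefficients,
                   intercept_sd = 2.464,
                   resid_model = quebec_o3_covariance(),
                   resid_sd = 8.904, seed = 1L, knots = default_knots()) {
  coeffs <- as_lur_coefficients(coeffs)
  if (intercept_sd < 0 || resid_sd < 0)
    stop("intercept_sd and resid_sd must be non-negative", call. = FALSE)
  design <- build_design(covariates, stations, knots)
  mu <- predict_fixed(coeffs, design)
  st_ids <- sort(unique(stations$station))
  days <- sort(unique(design$day))
  with_seed(seed, {
    u <- setNames(rnorm(length(st_ids), 0, intercept_sd), st_ids)
    if (resid_sd > 0) {
      Z <- sim_resid_field(stations[match(st_ids, stations$station), ],
                           days, resid_model, resid_sd)
      eps <- Z[cbind(match(design$station, st_ids),
                     match(design$day, days))]
    } else {
      Z <- matrix(0, length(st_ids), length(days))
      eps <- numeric(nrow(design))
    }
    o3 <- mu + u[design$station] + eps
    n_trunc <- sum(o3 < 0)
    hard <- data.frame(station = design$station, x = design$x,
                       y = design$y, day = design$day,
                       o3_ppb = pmax(o3, 0), stringsAsFactors = FALSE,
                       row.names = NULL)
    truth <- structure(list(coeffs = coeffs, intercepts = u,
                            intercept_sd = intercept_sd,
                            resid_model = resid_model,
                            resid_sd = resid_sd, seed = seed,
                            knots = knots, n_truncated = n_trunc,
                            resid_field = Z),
                       class = "sim_truth")
    list(hard = hard, truth = truth)
  })
}

#' Generate covariates at soft-data grid cells
#'
#' Builds the regular grid of cell centers implied by the region's
#' resolution, assigns each cell the meteorology of its nearest station
#' (emulating use of the closest weather monitor), draws a right-skewed
#' road density per cell and computes rescaled latitude from the region
#' origin.
#'
#' @param region A `region_spec`.
#' @param stations Station table providing meteorology sources.
#' @param covariates Station-day covariates from [gen_covariates()];
#'   station-days missing there are missing at the grid cells they feed.
#' @param seed Integer seed (road-density draws).
#' @param days Day indices to include (default: all region dates).
#' @param max_station_dist Keep only cells within this distance (km) of
#'   a station (default `Inf`, the whole region).  Restricting the grid
#'   to the monitored neighborhood keeps fine-resolution soft tables
#'   tractable; cells far from every station lack usable meteorology
#'   anyway.
#' @param station_cells Also emit one cell at each station location,
#'   carrying the station's own road density, latitude and meteorology.
#'   This emulates a grid fine enough to resolve the monitors (a 1-km
#'   grid always contains a cell sharing a monitor's road buffer),
#'   which a coarse desk-scale grid cannot represent otherwise.
#' @return Data frame with columns `x`, `y`, `day`, `doy`, `year`,
#'   `temperature`, `precipitation`, `road_density`, `latitude`.
#' @export
gen_grid_covariates <- function(region, stations, covariates, seed,
                                days = region$dates,
                                max_station_dist = Inf,
                                station_cells = FALSE) {
  stopifnot(inherits(region, "region_spec"))
  gr <- region$grid_resolution
  cx <- seq(region$x_extent[1] + gr / 2, region$x_extent[2], by = gr)
  cy <- seq(region$y_extent[1] + gr / 2, region$y_extent[2], by = gr)
  cells <- expand.grid(x = cx, y = cy)
  nn <- apply(cells, 1, function(p)
    which.min((stations$x - p[1])^2 + (stations$y - p[2])^2))
  nd <- sqrt((stations$x[nn] - cells$x)^2 + (stations$y[nn] - cells$y)^2)
  keep <- nd <= max_station_dist
  cells <- cells[keep, , drop = FALSE]
  nn <- nn[keep]
  cells$met_station <- stations$station[nn]
  with_seed(seed, {
    cells$road_density <- road_density_field(cells$x, cells$y, region)
  })
  # a cell containing a monitoring station shares the station's 1-km
  # road buffer, so it inherits the station's road density
  inside <- abs(stations$x[nn] - cells$x) <= gr / 2 &
    abs(stations$y[nn] - cells$y) <= gr / 2
  cells$road_density[inside] <- stations$road_density[nn[inside]]
  if (station_cells) {
    stc <- data.frame(x = stations$x, y = stations$y,
                      met_station = stations$station,
                      road_density = stations$road_density)
    cells <- rbind(cells[c("x", "y", "met_station", "road_density")],
                   stc)
  }
  # same origin as the station table: latitude 0 is the southernmost
  # monitoring station (cells south of it get negative values, which the
  # linear spline handles)
  cells$latitude <- cells$y - min(stations$y)
  cal <- region$calendar[region$calendar$day %in% days, , drop = FALSE]
  g <- merge(cells, cal, by = NULL)
  met <- covariates[c("station", "day", "temperature", "precipitation")]
  g <- merge(g, met, by.x = c("met_station", "day"),
             by.y = c("station", "day"), all.x = TRUE, sort = FALSE)
  g <- g[order(g$day, g$y, g$x), , drop = FALSE]
  data.frame(x = g$x, y = g$y, day = g$day, doy = g$doy, year = g$year,
             temperature = g$temperature, precipitation = g$precipitation,
             road_density = g$road_density, latitude = g$latitude,
             row.names = NULL)
}

#' Write a simulation truth record to JSON
#'
#' Serializes a `sim_truth` (without the residual matrix) so that a
#' generated data set can be audited and regenerated from its seed.
#'
#' @param truth A `sim_truth` from [gen_o3()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(coefficients = as.list(unclass(truth$coeffs)),
              intercepts = as.list(truth$intercepts),
              intercept_sd = truth$intercept_sd,
              resid_model = unclass(truth$resid_model)[
                c("w1", "s_range1", "t_range1", "w2", "s_range2",
                  "t_range2")],
              resid_sd = truth$resid_sd, seed = truth$seed,
              knots = as.list(truth$knots),
              n_truncated = truth$n_truncated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
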