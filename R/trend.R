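#' @name trend_normalize
#' @title Gaussian-kernel detrending and normal-score transformation
#'
#' @description
#' Before covariance modelling and estimation, ozone observations are
#' (i) detrended by subtracting a smooth space-time mean -- a Gaussian
#' kernel smoother with spatial bandwidth 25 km and temporal bandwidth
#' 2 days (interpreted as kernel SDs) -- and (ii) mapped to standard
#' normal scores by the rank-based n-score transform.  Both steps have
#' exact inverses on their fitting sets; estimates are back-transformed
#' in reverse order (denormalize, then retrend).  Gaussian soft data are
#' carried through the n-score map by transforming their means and
#' rescaling their SDs by the local slope of the map (first-order delta
#' method), preserving the Gaussian form required by the analytic
#' estimator.
NULL

#' Fit the Gaussian-kernel space-time trend
#'
#' The trend at any space-time point is the kernel-weighted mean of the
#' data, `m(s,t) = sum_i w_i z_i / sum_i w_i` with
#' `w_i = exp(-|s - s_i|^2 / (2 sbw^2)) * exp(-(t - t_i)^2 / (2 tbw^2))`.
#' Where all weights underflow to zero the overall data mean is
#' returned.
#'
#' @param data Data frame with columns `x`, `y`, `day` and `value_col`.
#' @param spatial_bw Spatial bandwidth (km), kernel SD.
#' @param temporal_bw Temporal bandwidth (days), kernel SD.
#' @param value_col Name of the value column.
#' @return Object of class `st_trend`.
#' @export
fit_trend <- function(data, spatial_bw = 25, temporal_bw = 2,
                      value_col = "o3_ppb") {
  if (nrow(data) < 1L) stop("trend requires at least 1 datum",
                            call. = FALSE)
  if (spatial_bw <= 0 || temporal_bw <= 0)
    stop("bandwidths must be strictly positive", call. = FALSE)
  if (!value_col %in% names(data))
    stop("data lacks column ", value_col, call. = FALSE)
  structure(list(x = data$x, y = data$y, day = data$day,
                 z = data[[value_col]], spatial_bw = spatial_bw,
                 temporal_bw = temporal_bw,
                 mean_z = mean(data[[value_col]])),
            class = "st_trend")
}

#' Evaluate a fitted trend at space-time points
#'
#' @param trend An `st_trend`.
#' @param x,y,day Coordinates (km) and day indices, equal length.
#' @return Trend values.
#' @export
trend_predict <- function(trend, x, y, day) {
  stopifnot(inherits(trend, "st_trend"))
  n <- length(x)
  out <- numeric(n)
  if (n == 0L) return(out)
  chunk <- max(1L, floor(2e6 / max(length(trend$z), 1L)))
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(x[ii], trend$x, "-")^2 + outer(y[ii], trend$y, "-")^2
    t2 <- outer(day[ii], trend$day, "-")^2
    w <- exp(-d2 / (2 * trend$spatial_bw^2) -
               t2 / (2 * trend$temporal_bw^2))
    sw <- rowSums(w)
    m <- as.vector(w %*% trend$z)
    out[ii] <- ifelse(sw > 0, m / pmax(sw, .Machine$double.xmin),
                      trend$mean_z)
  }
  out
}

#' Remove / restore the space-time trend
#'
#' `detrend()` subtracts the trend evaluated at each datum's location,
#' adding a `resid` column; `retrend()` adds it back into `value_col`.
#' The two are exact inverses: `retrend(detrend(x)) == x`.
#'
#' @param data Data frame with `x`, `y`, `day` and the relevant column.
#' @param trend An `st_trend`.
#' @param value_col Observed-value column name.
#' @param resid_col Residual column name.
#' @return The data frame with the added column.
#' @export
detrend <- function(data, trend, value_col = "o3_ppb",
                    resid_col = "resid") {
  m <- trend_predict(trend, data$x, data$y, data$day)
  data[[resid_col]] <- data[[value_col]] - m
  data
}

#' @rdname detrend
#' @export
retrend <- function(data, trend, resid_col = "resid",
                    value_col = "o3_ppb") {
  m <- trend_predict(trend, data$x, data$y, data$day)
  data[[value_col]] <- data[[resid_col]] + m
  data
}

#' Fit a normal-score (n-score) map
#'
#' Maps each value's tie-averaged empirical quantile
#' `p = (rank - 0.5) / n` to the standard-normal quantile `qnorm(p)`.
#' Between reference values the transform is piecewise linear; beyond
#' the extremes it extrapolates linearly with the slope of the end
#' segment.  The inverse is exact on the fitting set.
#'
#' @param values Numeric vector with at least 3 distinct finite values.
#' @return Object of class `nscore_map` with the strictly increasing
#'   reference values and matched normal quantiles.
#' @export
nscore_fit <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3L)
    stop("n-score fit requires at least 3 distinct values",
         call. = FALSE)
  r <- rank(values, ties.method = "average")
  z <- qnorm((r - 0.5) / length(values))
  o <- order(values)
  keep <- !duplicated(values[o])
  structure(list(v_ref = values[o][keep], z_ref = z[o][keep],
                 n = length(values)),
            class = "nscore_map")
}

# piecewise-linear interpolation with linear end extrapolation
interp_extrap <- function(xs, ys, x) {
  i <- findInterval(x, xs, all.inside = TRUE)
  slope <- (ys[i + 1L] - ys[i]) / (xs[i + 1L] - xs[i])
  ys[i] + slope * (x - xs[i])
}

#' Apply / invert / differentiate an n-score map
#'
#' `nscore_forward()` maps data values to normal scores,
#' `nscore_back()` inverts, and `nscore_slope()` returns the local
#' derivative dz/dv of the forward map (used to rescale Gaussian soft
#' SDs by the delta method).
#'
#' @param map An `nscore_map`.
#' @param v Data-scale values.
#' @param z Normal-score values.
#' @return Numeric vector.
#' @export
nscore_forward <- function(map, v) {
  stopifnot(inherits(map, "nscore_map"))
  interp_extrap(map$v_ref, map$z_ref, v)
}

#' @rdname nscore_forward
#' @export
nscore_back <- function(map, z) {
  stopifnot(inherits(map, "nscore_map"))
  interp_extrap(map$z_ref, map$v_ref, z)
}

#' @rdname nscore_forward
#' @export
nscore_slope <- function(map, v) {
  stopifnot(inherits(map, "nscore_map"))
  i <- findInterval(v, map$v_ref, all.inside = TRUE)
  (map$z_ref[i + 1L] - map$z_ref[i]) / (map$v_ref[i + 1L] - map$v_ref[i])
}

# slope of the inverse map at normal score z
nscore_back_slope <- function(map, z) {
  i <- findInterval(z, map$z_ref, all.inside = TRUE)
  (map$v_ref[i + 1L] - map$v_ref[i]) / (map$z_ref[i + 1L] - map$z_ref[i])
}

#' Export an n-score map as a two-column table
#'
#' @param map An `nscore_map`.
#' @return Data frame with columns `value` and `quantile` (normal
#'   score), suitable for audit or serialization.
#' @export
nscore_table <- function(map) {
  stopifnot(inherits(map, "nscore_map"))
  data.frame(value = map$v_ref, quantile = map$z_ref)
}

#' Fit the combined detrend + n-score transform on hard data
#'
#' The default pipeline order detrends first and then normal-scores the
#' residuals; inversion proceeds in reverse (denormalize, then retrend).
#' The alternative order (`"nscore_first"`) normal-scores the raw values
#' and then detrends the scores.
#'
#' @param hard Hard-data table (`x`, `y`, `day`, `value_col`).
#' @param spatial_bw,temporal_bw Kernel bandwidths (km, days).
#' @param order `"detrend_first"` (default) or `"nscore_first"`.
#' @param value_col Observed-value column.
#' @return Object of class `bme_transform`.
#' @export
fit_transform <- function(hard, spatial_bw = 25, temporal_bw = 2,
                          order = c("detrend_first", "nscore_first"),
                          value_col = "o3_ppb") {
  order <- match.arg(order)
  if (order == "detrend_first") {
    trend <- fit_trend(hard, spatial_bw, temporal_bw, value_col)
    res <- detrend(hard, trend, value_col)
    nmap <- nscore_fit(res$resid)
  } else {
    nmap <- nscore_fit(hard[[value_col]])
    hard$.ns <- nscore_forward(nmap, hard[[value_col]])
    trend <- fit_trend(hard, spatial_bw, temporal_bw, ".ns")
  }
  structure(list(order = order, trend = trend, nscore = nmap,
                 value_col = value_col),
            class = "bme_transform")
}

#' Transform hard data into the detrended n-score space
#'
#' @param tr A `bme_transform`.
#' @param hard Hard-data table with `x`, `y`, `day` and the value
#'   column.
#' @return The table with an added `z` column (transformed values).
#' @export
transform_hard <- function(tr, hard) {
  stopifnot(inherits(tr, "bme_transform"))
  v <- hard[[tr$value_col]]
  m <- trend_predict(tr$trend, hard$x, hard$y, hard$day)
  hard$z <- if (tr$order == "detrend_first")
    nscore_forward(tr$nscore, v - m)
  else nscore_forward(tr$nscore, v) - m
  hard
}

#' Transform Gaussian soft data into the detrended n-score space
#'
#' Soft means go through the same trend/n-score path as hard data; soft
#' SDs are rescaled by the local slope of the n-score map at the mean
#' (first-order delta method), keeping the soft records Gaussian.
#'
#' @param tr A `bme_transform`.
#' @param soft Soft-data table (`x`, `y`, `day`, `mean_ppb`, `sd_ppb`).
#' @return The table with added `mean_z` and `var_z` columns.
#' @export
transform_soft <- function(tr, soft) {
  stopifnot(inherits(tr, "bme_transform"))
  m <- trend_predict(tr$trend, soft$x, soft$y, soft$day)
  if (tr$order == "detrend_first") {
    res <- soft$mean_ppb - m
    soft$mean_z <- nscore_forward(tr$nscore, res)
    sl <- nscore_slope(tr$nscore, res)
  } else {
    soft$mean_z <- nscore_forward(tr$nscore, soft$mean_ppb) - m
    sl <- nscore_slope(tr$nscore, soft$mean_ppb)
  }
  soft$var_z <- (soft$sd_ppb * sl)^2
  soft
}

#' Back-transform estimates to the observation scale
#'
#' Inverts the transform at estimation points: denormalize, then
#' retrend.  The posterior SD is back-transformed by the delta method
#' (slope of the inverse n-score map at the estimate); a Monte-Carlo
#' alternative samples the transformed posterior, back-transforms the
#' draws and summarizes them (reference implementation; uses the
#' current RNG stream).
#'
#' @param tr A `bme_transform`.
#' @param x,y,day Estimation point coordinates.
#' @param mean_z,sd_z Posterior mean and SD in transformed space.
#' @param method `"delta"` (default) or `"mc"`.
#' @param nsim Monte-Carlo sample size for `method = "mc"`.
#' @return Data frame with columns `mean` and `sd` on the observation
#'   scale (ppb).
#' @export
back_transform <- function(tr, x, y, day, mean_z, sd_z,
                           method = c("delta", "mc"), nsim = 4000L) {
  stopifnot(inherits(tr, "bme_transform"))
  method <- match.arg(method)
  m <- trend_predict(tr$trend, x, y, day)
  if (method == "delta") {
    if (tr$order == "detrend_first") {
      v <- nscore_back(tr$nscore, mean_z) + m
      s <- sd_z * nscore_back_slope(tr$nscore, mean_z)
    } else {
      v <- nscore_back(tr$nscore, mean_z + m)
      s <- sd_z * nscore_back_slope(tr$nscore, mean_z + m)
    }
    return(data.frame(mean = v, sd = s))
  }
  n <- length(mean_z)
  out <- data.frame(mean = numeric(n), sd = numeric(n))
  for (i in seq_len(n)) {
    zz <- rnorm(nsim, mean_z[i], sd_z[i])
    vv <- if (tr$order == "detrend_first")
      nscore_back(tr$nscore, zz) + m[i]
    else nscore_back(tr$nscore, zz + m[i])
    out$mean[i] <- mean(vv); out$sd[i] <- sd(vv)
  }
  out
}
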