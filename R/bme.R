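#' @name bme_engine
#' @title Space-time estimation from hard and Gaussian soft data
#'
#' @description
#' Estimation at unmonitored space-time points runs in the detrended,
#' normal-scored space under the nested covariance model.  With hard
#' data only, the estimator is simple kriging (known zero mean, the mean
#' having been removed by detrending).  With Gaussian soft data the BME
#' posterior is available in closed form and reduces to kriging with
#' heteroscedastic data noise: the soft error variances enter the data
#' covariance diagonal.  The production path uses this analytic
#' solution; a numerical-integration oracle ([bme_numeric_oracle()])
#' evaluates the BME posterior integral by Gauss--Hermite quadrature and
#' exists purely to verify the analytic path.
NULL

#' Local estimation neighborhood configuration
#'
#' @param max_hard,max_soft Maximum numbers of hard and soft neighbors.
#' @param spatial_radius Search radius (km).
#' @param temporal_radius Search radius (days).
#' @return Object of class `neighborhood_config`.
#' @export
neighborhood_config <- function(max_hard = 10L, max_soft = 10L,
                                spatial_radius = 500,
                                temporal_radius = 60) {
  if (max_hard < 1L || max_soft < 1L)
    stop("neighbor counts must be at least 1", call. = FALSE)
  if (spatial_radius <= 0 || temporal_radius <= 0)
    stop("search radii must be strictly positive", call. = FALSE)
  structure(list(max_hard = as.integer(max_hard),
                 max_soft = as.integer(max_soft),
                 spatial_radius = spatial_radius,
                 temporal_radius = temporal_radius),
            class = "neighborhood_config")
}

# rank one table's rows as neighbors of `point`; returns kept row indices
rank_neighbors <- function(point, tab, max_n, config, model, id) {
  if (is.null(tab) || nrow(tab) == 0L) return(integer(0))
  d <- sqrt((tab$x - point$x)^2 + (tab$y - point$y)^2)
  dt <- abs(tab$day - point$day)
  keep <- which(d <= config$spatial_radius & dt <= config$temporal_radius)
  if (!length(keep)) return(integer(0))
  cv <- model_covariance(model, d[keep], dt[keep])
  ord <- order(-cv, d[keep], id[keep])
  keep[utils::head(ord, max_n)]
}

#' Select hard and soft neighbors of an estimation point
#'
#' Neighbors within the search radii are ranked by their model
#' covariance with the estimation point (descending) and truncated to
#' the configured maxima.  Ties are broken deterministically by distance
#' and then by station id (hard) or row order (soft), so the selection
#' is invariant to permutations of the input tables.
#'
#' @param point List or one-row data frame with `x`, `y`, `day`.
#' @param hard Transformed hard-data table (`x`, `y`, `day`, `z`,
#'   optionally `station`).
#' @param soft Transformed soft-data table (`x`, `y`, `day`, `mean_z`,
#'   `var_z`) or `NULL`.
#' @param config A [neighborhood_config()].
#' @param model An `stcov_model`.
#' @return List with integer index vectors `hard` and `soft`.
#' @export
select_neighbors <- function(point, hard, soft = NULL,
                             config = neighborhood_config(), model) {
  hid <- if (!is.null(hard$station)) hard$station
         else sprintf("%09d", seq_len(nrow(hard)))
  sid <- if (!is.null(soft)) sprintf("%09d", seq_len(nrow(soft)))
  list(hard = rank_neighbors(point, hard, config$max_hard, config, model,
                             hid),
       soft = if (is.null(soft)) integer(0)
              else rank_neighbors(point, soft, config$max_soft, config,
                                  model, sid))
}

#' Analytic Gaussian estimation from hard and soft neighbors
#'
#' Solves the zero-mean Gaussian system in transformed space: with
#' joint prior covariance `C`, data noise `N = diag(0 for hard, soft
#' error variances)`, the posterior mean is
#' `c0' (C_dd + N)^{-1} z` and the variance
#' `C00 - c0' (C_dd + N)^{-1} c0`, clamped to `[0, C00]`.  With no soft
#' data this is exact simple kriging.  A jitter ladder (1e-10 to 1e-6 on
#' the diagonal) is applied before declaring numerical failure.
#'
#' @param point Estimation point (`x`, `y`, `day`).
#' @param hard Hard neighbors (`x`, `y`, `day`, `z`); may be empty.
#' @param soft Soft neighbors (`x`, `y`, `day`, `mean_z`, `var_z`); may
#'   be empty or `NULL`.
#' @param model An `stcov_model`.
#' @return List with `mean`, `var` (transformed space) and `status`
#'   (`"ok"` or `"numerical-failure"`).
#' @export
solve_gaussian <- function(point, hard, soft = NULL, model) {
  nh <- if (is.null(hard)) 0L else nrow(hard)
  ns <- if (is.null(soft)) 0L else nrow(soft)
  if (nh + ns < 1L)
    stop("at least one neighbor is required", call. = FALSE)
  pts <- list(x = c(if (nh) hard$x, if (ns) soft$x),
              y = c(if (nh) hard$y, if (ns) soft$y),
              day = c(if (nh) hard$day, if (ns) soft$day))
  z <- c(if (nh) hard$z, if (ns) soft$mean_z)
  noise <- c(rep(0, nh), if (ns) soft$var_z)
  Cdd <- stcov_cross(model, pts, pts)
  c0 <- drop(stcov_cross(model, point, pts))
  C00 <- model_covariance(model, 0, 0)
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    A <- Cdd + diag(noise + j, nh + ns)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (!is.null(ch)) {
      wz <- backsolve(ch, forwardsolve(t(ch), z))
      wc <- backsolve(ch, forwardsolve(t(ch), c0))
      v <- C00 - sum(c0 * wc)
      return(list(mean = sum(c0 * wz),
                  var = min(max(v, 0), C00), status = "ok"))
    }
  }
  list(mean = NA_real_, var = NA_real_, status = "numerical-failure")
}

#' Numerical-integration reference for the BME posterior
#'
#' Computes the posterior moments at the estimation point by direct
#' numerical integration of the BME posterior density
#' `f(x0) proportional to integral f_Gauss(x0, x_s | x_h) prod_j
#' f_soft(x_s_j) d x_s` over the soft values, on a tensor Gauss--Hermite
#' grid centered on the soft means.  Restricted to at most 3 soft
#' neighbors (quadrature cost).  With Gaussian soft densities this
#' agrees with the analytic [solve_gaussian()] solution to quadrature
#' accuracy; the function exists to verify that path, not to replace
#' it.  Doubling the node count must change the moments by less than
#' `tol`, else a convergence error is raised.
#'
#' @param point Estimation point (`x`, `y`, `day`).
#' @param hard Hard neighbors; may be empty.
#' @param soft Soft neighbors (at most 3 rows); may be empty.
#' @param model An `stcov_model`.
#' @param n_nodes Gauss--Hermite nodes per soft dimension.
#' @param tol Convergence tolerance on the moments.
#' @return List with `mean` and `var` in transformed space.
#' @export
bme_numeric_oracle <- function(point, hard, soft = NULL, model,
                               n_nodes = 40L, tol = 1e-8) {
  nh <- if (is.null(hard)) 0L else nrow(hard)
  ns <- if (is.null(soft)) 0L else nrow(soft)
  if (ns > 3L)
    stop("the quadrature oracle supports at most 3 soft neighbors",
         call. = FALSE)
  if (nh + ns < 1L)
    stop("at least one neighbor is required", call. = FALSE)
  moments <- function(nn) {
    if (ns == 0L) {
      sol <- solve_gaussian(point, hard, NULL, model)
      return(c(sol$mean, sol$var))
    }
    all_pts <- list(x = c(point$x, soft$x, if (nh) hard$x),
                    y = c(point$y, soft$y, if (nh) hard$y),
                    day = c(point$day, soft$day, if (nh) hard$day))
    C <- stcov_cross(model, all_pts, all_pts)
    i0s <- seq_len(1L + ns)
    if (nh > 0L) {
      ih <- (1L + ns) + seq_len(nh)
      Khh <- C[ih, ih, drop = FALSE]
      diag(Khh) <- diag(Khh) + 1e-12
      K <- C[i0s, ih, drop = FALSE] %*% solve(Khh)
      m_c <- drop(K %*% hard$z)
      S <- C[i0s, i0s, drop = FALSE] - K %*% C[ih, i0s, drop = FALSE]
    } else {
      m_c <- rep(0, 1L + ns)
      S <- C[i0s, i0s, drop = FALSE]
    }
    S <- (S + t(S)) / 2
    m0 <- m_c[1L]; ms <- m_c[-1L]
    S00 <- S[1L, 1L]; S0s <- S[1L, -1L, drop = FALSE]
    Sss <- S[-1L, -1L, drop = FALSE]
    Sss_r <- Sss; diag(Sss_r) <- diag(Sss_r) + 1e-12
    A <- S0s %*% solve(Sss_r)
    vcond <- max(S00 - drop(A %*% t(S0s)), 0)
    gh <- pracma::gaussHermite(nn)
    grids <- lapply(seq_len(ns), function(j)
      soft$mean_z[j] + sqrt(2 * soft$var_z[j]) * gh$x)
    xs <- as.matrix(expand.grid(grids))
    wq <- apply(as.matrix(expand.grid(rep(list(gh$w), ns))), 1, prod)
    # N(xs; ms, Sss) density (log), chol-based
    ch <- chol(Sss_r)
    dev <- forwardsolve(t(ch), t(xs) - ms)
    logdens <- -0.5 * colSums(dev^2) - sum(log(diag(ch))) -
      (ns / 2) * log(2 * pi)
    lw <- log(wq) + logdens
    lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
    a <- m0 + drop(A %*% (t(xs) - ms))
    mu <- sum(w * a)
    c(mu, vcond + sum(w * a^2) - mu^2)
  }
  m1 <- moments(n_nodes)
  if (ns > 0L) {
    m2 <- moments(2L * n_nodes)
    if (max(abs(m2 - m1)) > tol)
      stop("quadrature did not converge: moment change ",
           format(max(abs(m2 - m1))), " when doubling nodes",
           call. = FALSE)
    m1 <- m2
  }
  list(mean = m1[1], var = max(m1[2], 0))
}

#' Estimate ozone at target points (kriging or BME-LUR)
#'
#' Runs the full per-point pipeline: transform hard (and soft) data into
#' the detrended n-score space, select neighbors, solve the Gaussian
#' system, and back-transform (denormalize, then retrend).  Failures are
#' first-class outcomes: points with no neighbors or a singular system
#' are returned with a status flag, never dropped silently.  Optionally
#' a soft/hard conflict check flags points whose hard neighbor values
#' all lie more than `soft_conflict_sd` soft SDs outside the soft range
#' (the estimation-failure mode seen when observed values far exceed the
#' soft data's support) as `"numerical-failure"`.
#'
#' @param targets Data frame of estimation points (`x`, `y`, `day`).
#' @param hard Hard-data table on the observation scale (`station`, `x`,
#'   `y`, `day`, `o3_ppb`).
#' @param soft Soft-data table (`x`, `y`, `day`, `mean_ppb`, `sd_ppb`)
#'   or `NULL`.
#' @param model An `stcov_model`.
#' @param transform A `bme_transform` fitted on the hard data (default:
#'   fitted here with default bandwidths).
#' @param config A [neighborhood_config()].
#' @param mode `"bme"` (hard + soft; the BME-LUR) or `"kriging"` (hard
#'   only).  Kriging ignores `soft` entirely.
#' @param back Back-transform method, `"delta"` or `"mc"`.
#' @param soft_conflict_sd Threshold (in soft SDs) for the conflict
#'   check; `Inf` (default) disables it.
#' @return Data frame with columns `x`, `y`, `day`, `mean_ppb`,
#'   `sd_ppb`, `n_hard`, `n_soft`, `status`.
#' @export
estimate_points <- function(targets, hard, soft = NULL, model,
                            transform = NULL,
                            config = neighborhood_config(),
                            mode = c("bme", "kriging"),
                            back = c("delta", "mc"),
                            soft_conflict_sd = Inf) {
  mode <- match.arg(mode)
  back <- match.arg(back)
  if (is.null(transform)) transform <- fit_transform(hard)
  hz <- transform_hard(transform, hard)
  sz <- if (mode == "bme" && !is.null(soft) && nrow(soft) > 0L)
    transform_soft(transform, soft)
  n <- nrow(targets)
  out <- data.frame(x = targets$x, y = targets$y, day = targets$day,
                    mean_ppb = NA_real_, sd_ppb = NA_real_,
                    n_hard = 0L, n_soft = 0L, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pt <- list(x = targets$x[i], y = targets$y[i], day = targets$day[i])
    nb <- select_neighbors(pt, hz, sz, config, model)
    hs <- hz[nb$hard, , drop = FALSE]
    ss <- if (!is.null(sz)) sz[nb$soft, , drop = FALSE]
    out$n_hard[i] <- nrow(hs)
    out$n_soft[i] <- if (is.null(ss)) 0L else nrow(ss)
    if (out$n_hard[i] + out$n_soft[i] == 0L) {
      out$status[i] <- "no-neighbors"
      next
    }
    if (is.finite(soft_conflict_sd) && out$n_soft[i] > 0L &&
        out$n_hard[i] > 0L) {
      lo <- min(ss$mean_z - soft_conflict_sd * sqrt(ss$var_z))
      hi <- max(ss$mean_z + soft_conflict_sd * sqrt(ss$var_z))
      if (min(hs$z) > hi || max(hs$z) < lo) {
        out$status[i] <- "numerical-failure"
        next
      }
    }
    sol <- solve_gaussian(pt, hs, ss, model)
    if (sol$status != "ok") {
      out$status[i] <- sol$status
      next
    }
    bt <- back_transform(transform, pt$x, pt$y, pt$day, sol$mean,
                         sqrt(sol$var), method = back)
    out$mean_ppb[i] <- bt$mean
    out$sd_ppb[i] <- bt$sd
  }
  out
}
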