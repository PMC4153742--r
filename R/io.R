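#' @name cli_io
#' @title File formats, schema-validated IO and pipeline stages
#'
#' @description
#' All tables are comma-separated UTF-8 with a header row; day indices
#' are integers (day 121 of year 0 is the first season day) and
#' coordinates are plain planar km.  [read_table()] and [write_table()]
#' validate against named schemas; the `run_*` stage functions chain the
#' pipeline on disk, each writing its outputs plus a JSON manifest with
#' the seed, parameters and input checksums, so re-running a stage with
#' unchanged inputs is idempotent.
NULL

bmelur_schemas <- list(
  stations  = list(cols = c(station = "character", x = "numeric",
                            y = "numeric", road_density = "numeric",
                            latitude = "numeric"),
                   key = "station"),
  covariates = list(cols = c(station = "character", day = "integer",
                             doy = "integer", year = "integer",
                             temperature = "numeric",
                             precipitation = "numeric"),
                    key = c("station", "day")),
  hard = list(cols = c(station = "character", x = "numeric",
                       y = "numeric", day = "integer",
                       o3_ppb = "numeric"),
              key = c("station", "day")),
  soft = list(cols = c(x = "numeric", y = "numeric", day = "integer",
                       mean_ppb = "numeric", sd_ppb = "numeric"),
              key = NULL),
  estimates = list(cols = c(x = "numeric", y = "numeric",
                            day = "integer", mean_ppb = "numeric",
                            sd_ppb = "numeric", n_hard = "integer",
                            n_soft = "integer", status = "character"),
                   key = NULL),
  cv = list(cols = c(station = "character", day = "integer",
                     observed = "numeric", est_lur = "numeric",
                     est_kriging = "numeric", est_bme = "numeric",
                     status_kriging = "character",
                     status_bme = "character", audit_ok = "logical"),
            key = c("station", "day")))

check_schema <- function(df, schema_name, where = "table") {
  sch <- bmelur_schemas[[schema_name]]
  if (is.null(sch)) stop("unknown schema: ", schema_name, call. = FALSE)
  miss <- setdiff(names(sch$cols), names(df))
  if (length(miss))
    stop("schema '", schema_name, "': ", where, " lacks column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cn in names(sch$cols)) {
    type <- sch$cols[[cn]]
    v <- df[[cn]]
    bad <- switch(type,
      numeric = !is.numeric(v),
      integer = !(is.numeric(v) && all(is.na(v) | v == round(v))),
      character = !(is.character(v) || is.factor(v)),
      logical = !is.logical(v))
    if (isTRUE(bad)) {
      row <- which(!is.na(v))[1]
      stop("schema '", schema_name, "': column ", cn,
           " has invalid type/value (e.g. row ",
           ifelse(is.na(row), 1, row), ")", call. = FALSE)
    }
  }
  if (!is.null(sch$key)) {
    key <- do.call(paste, c(df[sch$key], sep = "\r"))
    d <- duplicated(key)
    if (any(d))
      stop("schema '", schema_name, "': duplicate key (",
           paste(sch$key, collapse = ", "), ") = ",
           gsub("\r", ", ", key[which(d)[1]]), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a schema-validated delimited table
#'
#' @param path CSV file path.
#' @param schema One of `"stations"`, `"covariates"`, `"hard"`,
#'   `"soft"`, `"estimates"`, `"cv"`.
#' @param df Data frame to write.
#' @return `read_table()`: the validated data frame; `write_table()`:
#'   `path`, invisibly.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, schema, where = path)
  df
}

#' @rdname read_table
#' @export
write_table <- function(df, path, schema) {
  check_schema(df, schema)
  utils::write.csv(df[names(bmelur_schemas[[schema]]$cols)], path,
                   row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param output_dir Directory receiving stage artifacts.
#' @param seed Integer seed used by every stochastic stage.
#' @param region A [region_spec()].
#' @param missing_rate Covariate missingness rate for simulation.
#' @param spatial_bw,temporal_bw Detrending bandwidths (km, days).
#' @param nbr A [neighborhood_config()].
#' @param cv A [cv_config()].
#' @param estimate_days Day indices at which [run_estimate()] predicts
#'   the grid (default: first 5 region dates).
#' @param verbose Stage-level progress messages?
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, region = region_spec(),
                       missing_rate = 0.05, spatial_bw = 25,
                       temporal_bw = 2, nbr = neighborhood_config(),
                       cv = cv_config(),
                       estimate_days = utils::head(region$dates, 5),
                       verbose = TRUE) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 region = region, missing_rate = missing_rate,
                 spatial_bw = spatial_bw, temporal_bw = temporal_bw,
                 nbr = nbr, cv = cv, estimate_days = estimate_days,
                 verbose = verbose),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [run_config()] arguments (scalar fields
#' plus nested `region`, `nbr` and `cv` blocks); absent keys fall back
#' to the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  region <- if (is.null(y$region)) region_spec()
            else do.call(region_spec, y$region)
  nbr <- if (is.null(y$nbr)) neighborhood_config()
         else do.call(neighborhood_config, y$nbr)
  cv <- if (is.null(y$cv)) cv_config() else do.call(cv_config, y$cv)
  args <- y[intersect(names(y), c("output_dir", "seed", "missing_rate",
                                  "spatial_bw", "temporal_bw",
                                  "estimate_days", "verbose"))]
  do.call(run_config, c(args, list(region = region, nbr = nbr, cv = cv)))
}

stage_path <- function(config, file) file.path(config$output_dir, file)

stage_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[bmelur] ", ...)
}

require_artifact <- function(config, file, producer) {
  p <- stage_path(config, file)
  if (!file.exists(p))
    stop("dependency error: missing upstream artifact '", file,
         "'; run ", producer, "() first", call. = FALSE)
  p
}

write_manifest <- function(config, stage, inputs, outputs,
                           params = list()) {
  all_files <- c(inputs, outputs)
  sums <- as.list(tools::md5sum(all_files[file.exists(all_files)]))
  man <- list(stage = stage, seed = config$seed, params = params,
              inputs = inputs, outputs = outputs, md5 = sums)
  jsonlite::write_json(man,
                       stage_path(config, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline stages
#'
#' Each stage consumes the previous stage's on-disk artifacts from
#' `config$output_dir`, writes its own outputs plus a
#' `<stage>.manifest.json` (seed, parameters, checksums), and returns
#' its main result invisibly.  Missing upstream artifacts raise an
#' explicit dependency error.
#'
#' * `run_simulate()`: stations, covariates and hard data
#'   (`stations.csv`, `covariates.csv`, `hard.csv`, `truth.json`);
#' * `run_lur()`: LUR fit (`lur_fit.csv`) and soft data (`soft.csv`);
#' * `run_covfit()`: empirical covariance (`empirical_covariance.csv`)
#'   and fitted model (`cov_model.json`);
#' * `run_estimate()`: gridded estimates (`estimates.csv`);
#' * `run_cv()`: cross-validation records (`cv_records.csv`) and a
#'   metrics report (`cv_metrics.csv`, `report.md`).
#'
#' @param config A [run_config()].
#' @return The stage's main object, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage_msg(config, "simulate: generating network and observations")
  stations <- gen_network(config$region, config$seed)
  covs <- gen_covariates(stations, config$region, config$seed + 1L,
                         missing_rate = config$missing_rate)
  sim <- gen_o3(covs, stations, seed = config$seed + 2L)
  write_table(stations, stage_path(config, "stations.csv"), "stations")
  write_table(covs, stage_path(config, "covariates.csv"), "covariates")
  write_table(sim$hard, stage_path(config, "hard.csv"), "hard")
  write_sim_truth(sim$truth, stage_path(config, "truth.json"))
  write_manifest(config, "simulate", character(0),
                 stage_path(config, c("stations.csv", "covariates.csv",
                                      "hard.csv", "truth.json")),
                 list(missing_rate = config$missing_rate))
  invisible(sim)
}

#' @rdname run_simulate
#' @export
run_lur <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ps <- require_artifact(config, "stations.csv", "run_simulate")
  pc <- require_artifact(config, "covariates.csv", "run_simulate")
  ph <- require_artifact(config, "hard.csv", "run_simulate")
  stage_msg(config, "lur: fitting mixed model and building soft data")
  stations <- read_table(ps, "stations")
  covs <- read_table(pc, "covariates")
  hard <- read_table(ph, "hard")
  design <- build_design(covs, stations)
  key <- match(paste(design$station, design$day),
               paste(hard$station, hard$day))
  ok <- !is.na(key)
  fit <- fit_lur(design[ok, , drop = FALSE], hard$o3_ppb[key[ok]])
  ft <- data.frame(term = c(names(fit$coefficients), "sigma_u",
                            "sigma_e"),
                   estimate = c(unclass(fit$coefficients), fit$sigma_u,
                                fit$sigma_e),
                   se = c(fit$se, NA, NA))
  utils::write.csv(ft, stage_path(config, "lur_fit.csv"),
                   row.names = FALSE)
  grid <- gen_grid_covariates(config$region, stations, covs,
                              config$seed + 3L)
  soft <- make_soft_data(fit, grid)
  write_table(soft, stage_path(config, "soft.csv"), "soft")
  write_manifest(config, "lur", c(ps, pc, ph),
                 stage_path(config, c("lur_fit.csv", "soft.csv")),
                 list(n_design = sum(ok),
                      n_soft_skipped = attr(soft, "skipped")))
  invisible(fit)
}

#' @rdname run_simulate
#' @export
run_covfit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ph <- require_artifact(config, "hard.csv", "run_simulate")
  stage_msg(config, "covfit: empirical covariance and model fit")
  hard <- read_table(ph, "hard")
  tr <- fit_transform(hard, config$spatial_bw, config$temporal_bw)
  hz <- transform_hard(tr, hard)
  hz$resid <- hz$z
  emp <- empirical_covariance(hz)
  model <- fit_covariance(emp)
  utils::write.csv(emp, stage_path(config, "empirical_covariance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(unclass(model)[c("w1", "s_range1", "t_range1", "w2", "s_range2",
                       "t_range2")],
      list(objective = attr(model, "fit")$objective)),
    stage_path(config, "cov_model.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(config, "covfit", ph,
                 stage_path(config, c("empirical_covariance.csv",
                                      "cov_model.json")),
                 list(spatial_bw = config$spatial_bw,
                      temporal_bw = config$temporal_bw))
  invisible(model)
}

read_cov_artifact <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stcov_model(w1 = j$w1, s_range1 = j$s_range1, t_range1 = j$t_range1,
              w2 = j$w2, s_range2 = j$s_range2, t_range2 = j$t_range2)
}

#' @rdname run_simulate
#' @export
run_estimate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ph <- require_artifact(config, "hard.csv", "run_simulate")
  pso <- require_artifact(config, "soft.csv", "run_lur")
  pcv <- require_artifact(config, "cov_model.json", "run_covfit")
  stage_msg(config, "estimate: gridded BME-LUR estimation")
  hard <- read_table(ph, "hard")
  soft <- read_table(pso, "soft")
  model <- read_cov_artifact(pcv)
  tr <- fit_transform(hard, config$spatial_bw, config$temporal_bw)
  gr <- config$region$grid_resolution
  cx <- seq(config$region$x_extent[1] + gr / 2, config$region$x_extent[2],
            by = gr)
  cy <- seq(config$region$y_extent[1] + gr / 2, config$region$y_extent[2],
            by = gr)
  targets <- merge(expand.grid(x = cx, y = cy),
                   data.frame(day = config$estimate_days), by = NULL)
  est <- estimate_points(targets, hard, soft, model, tr, config$nbr)
  write_table(est, stage_path(config, "estimates.csv"), "estimates")
  write_manifest(config, "estimate", c(ph, pso, pcv),
                 stage_path(config, "estimates.csv"),
                 list(days = config$estimate_days))
  invisible(est)
}

#' @rdname run_simulate
#' @export
run_cv <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ph <- require_artifact(config, "hard.csv", "run_simulate")
  ps <- require_artifact(config, "stations.csv", "run_simulate")
  pc <- require_artifact(config, "covariates.csv", "run_simulate")
  pso <- require_artifact(config, "soft.csv", "run_lur")
  plf <- require_artifact(config, "lur_fit.csv", "run_lur")
  pcv <- require_artifact(config, "cov_model.json", "run_covfit")
  stage_msg(config, "cv: leave-one-station-out cross-validation")
  hard <- read_table(ph, "hard")
  stations <- read_table(ps, "stations")
  covs <- read_table(pc, "covariates")
  soft <- read_table(pso, "soft")
  model <- read_cov_artifact(pcv)
  ft <- utils::read.csv(plf, stringsAsFactors = FALSE)
  beta <- lur_coefficients(setNames(ft$estimate, ft$term)[lur_terms])
  design <- build_design(covs, stations)
  lur_pred <- data.frame(station = design$station, day = design$day,
                         pred = predict_fixed(beta, design))
  tr <- fit_transform(hard, config$spatial_bw, config$temporal_bw)
  rec <- loso_cv(hard, soft, model, tr, lur_pred, config$cv, config$nbr)
  met <- cv_metrics(rec, threshold = config$cv$threshold)
  write_table(rec, stage_path(config, "cv_records.csv"), "cv")
  utils::write.csv(met, stage_path(config, "cv_metrics.csv"),
                   row.names = FALSE)
  rep_lines <- c("# Cross-validation report", "",
                 paste0("Seed: ", config$seed, "; evaluation points: ",
                        nrow(rec)), "",
                 "| Method | R2 | RMSE (ppb) | PCMSE |",
                 "|---|---|---|---|",
                 sprintf("| %s | %.3f | %.3f | %s |", met$model, met$r2,
                         met$rmse,
                         ifelse(is.na(met$pcmse), "--",
                                sprintf("%.1f%%", met$pcmse))))
  writeLines(rep_lines, stage_path(config, "report.md"))
  write_manifest(config, "cv", c(ph, ps, pc, pso, plf, pcv),
                 stage_path(config, c("cv_records.csv", "cv_metrics.csv",
                                      "report.md")),
                 list(exclusion_window = config$cv$exclusion_window,
                      threshold = config$cv$threshold))
  invisible(list(records = rec, metrics = met))
}
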