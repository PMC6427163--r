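#' Write a daily series to CSV
#'
#' Columns: `date` (ISO-8601), `deaths`, `pm25` (ug/m3), `swt` (1-6),
#' `dow` (0-6).  Numeric columns are written with full double
#' precision so a round-trip through [read_series()] is lossless.
#'
#' @param series either a [simulate_series()] result or a
#'   `covariate_series`.
#' @param path output file path.
#' @param deaths death vector, required when `series` is a bare
#'   covariate series.
#' @return the path, invisibly.
#' @export
write_series <- function(series, path, deaths = NULL) {
  if (inherits(series, "covariate_series")) {
    cov <- series
    if (is.null(deaths)) stop("'deaths' required", call. = FALSE)
  } else {
    cov <- series$covariates
    deaths <- series$deaths
  }
  df <- data.frame(date = format(cov$date, "%Y-%m-%d"),
                   deaths = format(deaths, digits = 17, trim = TRUE,
                                   scientific = FALSE),
                   pm25 = format(cov$pm25, digits = 17, trim = TRUE,
                                 scientific = FALSE),
                   swt = cov$swt, dow = cov$dow)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily series from CSV
#'
#' Accepts any column order (header-keyed); requires columns `date`,
#' `deaths`, `pm25`, `swt`, `dow`, strictly increasing dates, and at
#' least 8 days (so that lags 1..7 leave at least one usable day).
#' Lag columns are reconstructed by shifting the PM2.5 series, so the
#' first 7 days carry `NA` lags and are dropped by the fitting
#' functions.
#'
#' @param path CSV file path.
#' @return list with `covariates` (a `covariate_series` without
#'   pre-period history) and `deaths`.
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "deaths", "pm25", "swt", "dow")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(df)
  if (n < 8)
    stop("series too short: need at least 8 days for lags 1..7",
         call. = FALSE)
  dates <- as.Date(df$date)
  if (anyNA(dates) || any(diff(as.numeric(dates)) <= 0))
    stop("'date' must be parseable and strictly increasing", call. = FALSE)
  if (any(!(df$swt %in% 1:6)) || any(!(df$dow %in% 0:6)))
    stop("'swt' must be in 1..6 and 'dow' in 0..6", call. = FALSE)
  pm <- as.numeric(df$pm25)
  lags <- sapply(1:7, function(l) c(rep(NA_real_, l), pm[seq_len(n - l)]) / 10)
  colnames(lags) <- paste0("lag", 1:7)
  cov <- structure(list(n_days = n, t = seq_len(n), date = dates,
                        pm25 = pm, pm25_history = rep(NA_real_, 7),
                        lags = lags, swt = as.integer(df$swt),
                        dow = as.integer(df$dow), seed = NA),
                   class = "covariate_series")
  list(covariates = cov, deaths = as.numeric(df$deaths))
}

config_defaults <- function(study) {
  list(study = study, n_days = 1096,
       gamma = if (study == 1) c(0.5, 1.0) else 0.5,
       df_per_year = if (study == 1) c(1, 2, 4, 8, 10, 16) else 8,
       replicates = c(100, 25),
       base_seed = 1000, covariate_seed = 101,
       engine = if (study == 1) "both" else "bayes",
       prior_mean = c(0.001, 0.005, 0.010, 0.020),
       prior_var_factor = c(0.5, 1.0),
       true_beta1 = c(0.001, 0.005, 0.010, 0.020),
       burn_in = 1000, iterations = 2000,
       out_dir = ".", verbose = FALSE)
}

#' Load and validate a study configuration
#'
#' Reads a YAML configuration, rejects unknown keys, validates field
#' values (naming the offending field) and fills defaults.  `study` is
#' the only required key.  Seeds are part of the configuration (never
#' wall-clock) so study runs are reproducible.
#'
#' @param path YAML file path.
#' @return object of class `"run_config"` (a named list).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$study))
    stop("config error: 'study' is required", call. = FALSE)
  if (!(raw$study %in% 1:3))
    stop("config error in 'study': must be 1, 2 or 3", call. = FALSE)
  cfg <- config_defaults(raw$study)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("config error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(raw)] <- raw
  if (any(cfg$gamma < 0))
    stop("config error in 'gamma': must be >= 0", call. = FALSE)
  if (any(cfg$df_per_year < 1))
    stop("config error in 'df_per_year': must be >= 1", call. = FALSE)
  if (any(cfg$replicates < 1))
    stop("config error in 'replicates': must be >= 1", call. = FALSE)
  if (cfg$n_days < 8)
    stop("config error in 'n_days': must be >= 8", call. = FALSE)
  if (!(cfg$engine %in% c("freq", "bayes", "both")))
    stop("config error in 'engine': must be freq, bayes or both",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a configuration back to YAML
#'
#' Writes the fully resolved (defaults filled) configuration, so
#' `load_config(dump_config(cfg))` reproduces `cfg` exactly.
#'
#' @param config a `"run_config"`.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a configured study and write its outputs
#'
#' Dispatches to [run_study1()], [run_study2()] or [run_study3()] and
#' writes `records.csv`, `summary.csv`, `regression.json` (study 3)
#' and a `provenance.json` block (config hash, seeds, package version)
#' into `config$out_dir`.
#'
#' @param config a [load_config()] result (or a list with the same
#'   fields).
#' @param model generative [true_model()].
#' @return the study result list, invisibly.
#' @export
run_study <- function(config, model = true_model()) {
  grid <- study_grid(study = config$study, gamma = config$gamma,
                     df_per_year = config$df_per_year,
                     prior_mean = config$prior_mean,
                     prior_var_factor = config$prior_var_factor,
                     true_beta1 = config$true_beta1,
                     replicates = config$replicates,
                     base_seed = config$base_seed,
                     covariate_seed = config$covariate_seed,
                     n_days = config$n_days, engine = config$engine,
                     burn_in = config$burn_in,
                     iterations = config$iterations)
  runner <- switch(config$study, run_study1, run_study2, run_study3)
  res <- runner(grid, model = model, progress = isTRUE(config$verbose))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(res$regression))
    jsonlite::write_json(res$regression,
                         file.path(out_dir, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile(fileext = ".yaml")
  dump_config(structure(config, class = "run_config"), cfg_file)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_file)),
               base_seed = config$base_seed,
               covariate_seed = config$covariate_seed,
               package_version =
                 as.character(utils::packageVersion("bgamsim")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(cfg_file)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
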