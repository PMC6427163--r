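#' Grid specification for the simulation studies
#'
#' Desk-scale defaults: study 1 crosses noise multipliers
#' `gamma = {0.5, 1.0}` with smooth flexibility
#' `df = {1, 2, 4, 8, 10, 16}` per year (100 frequentist / 25 Bayesian
#' replicates per cell); study 2 sweeps the prior mean of the lag-1
#' coefficient over `{0.001, 0.005, 0.010, 0.020}` with prior variance
#' `{0.5, 1.0}` times the mean; study 3 sweeps the generative truth
#' over the same values.  The full-size grids of the original analyses
#' (gamma in 0.5..1.0 by 0.1, df 1..20, 20 prior means / truths by
#' 0.001, 100 replicates everywhere) are obtained with `full = TRUE`.
#'
#' @param study 1, 2 or 3.
#' @param gamma noise multipliers (study 1).
#' @param df_per_year smooth df grid (study 1).
#' @param prior_mean prior-mean grid for the lag-1 coefficient
#'   (study 2).
#' @param prior_var_factor prior variance as a multiple of the prior
#'   mean (studies 2 and 3).
#' @param true_beta1 generative lag-1 coefficient grid (study 3).
#' @param replicates series per cell (for study 1, a length-2 vector
#'   `c(freq, bayes)` is allowed).
#' @param base_seed base RNG seed; replicate `r` of a cell uses noise
#'   seed `base_seed + r` and an MCMC seed offset by `10^5`.
#' @param covariate_seed seed of the single covariate draw shared by
#'   every cell of the study (preserving the concurvity between the
#'   exposure and the trend across replicates).
#' @param n_days series length.
#' @param engine `"freq"`, `"bayes"` or `"both"` (study 1 only).
#' @param burn_in,iterations MCMC settings for Bayesian cells.
#' @param full use the full-size grids.
#' @return object of class `"study_grid"`.
#' @export
study_grid <- function(study = 1,
                       gamma = c(0.5, 1.0),
                       df_per_year = c(1, 2, 4, 8, 10, 16),
                       prior_mean = c(0.001, 0.005, 0.010, 0.020),
                       prior_var_factor = c(0.5, 1.0),
                       true_beta1 = c(0.001, 0.005, 0.010, 0.020),
                       replicates = c(100, 25),
                       base_seed = 1000, covariate_seed = 101,
                       n_days = 1096, engine = c("both", "freq", "bayes"),
                       burn_in = 1000, iterations = 2000, full = FALSE) {
  engine <- match.arg(engine)
  if (!(study %in% 1:3)) stop("'study' must be 1, 2 or 3", call. = FALSE)
  if (full) {
    gamma <- seq(0.5, 1.0, by = 0.1)
    df_per_year <- 1:20
    prior_mean <- seq(0.001, 0.020, by = 0.001)
    prior_var_factor <- seq(0.5, 1.0, by = 0.1)
    true_beta1 <- seq(0.001, 0.020, by = 0.001)
    replicates <- c(100, 100)
  }
  if (length(replicates) == 1) replicates <- rep(replicates, 2)
  if (any(replicates < 1)) stop("'replicates' must be >= 1", call. = FALSE)
  if (!length(gamma) || !length(df_per_year) || !length(prior_mean) ||
      !length(true_beta1))
    stop("grids must be nonempty", call. = FALSE)
  structure(list(study = study, gamma = gamma, df_per_year = df_per_year,
                 prior_mean = prior_mean,
                 prior_var_factor = prior_var_factor,
                 true_beta1 = true_beta1, replicates = replicates,
                 base_seed = base_seed, covariate_seed = covariate_seed,
                 n_days = n_days, engine = engine, burn_in = burn_in,
                 iterations = iterations),
            class = "study_grid")
}

# one frequentist or Bayesian fit -> a record row; failures flagged
fit_one <- function(sim, engine, spec, priors, mcmc) {
  rec <- tryCatch({
    if (engine == "freq") {
      f <- fit_fgam(sim, spec)
      list(beta1 = unname(coef(f)["lag1"]), sd = unname(f$se["lag1"]),
           ok = TRUE)
    } else {
      f <- fit_bgam(sim, spec, priors, mcmc)
      s <- f$summary[f$summary$parameter == "lag1", ]
      list(beta1 = s$mean, sd = s$sd, ok = TRUE)
    }
  }, error = function(e) list(beta1 = NA_real_, sd = NA_real_, ok = FALSE))
  rec
}

run_cells <- function(cells, grid, model, covariates, progress = FALSE) {
  rows <- vector("list", nrow(cells) * max(grid$replicates))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    n_rep <- if (cell$engine == "freq") grid$replicates[1] else grid$replicates[2]
    m <- model
    m$gamma <- cell$gamma
    if (!is.na(cell$true_beta1)) m$beta_lag[1] <- cell$true_beta1
    spec <- gam_spec(df_per_year = cell$df_per_year)
    priors <- NULL
    if (cell$engine == "bayes") {
      cp <- if (!is.na(cell$prior_mean))
        list(lag1 = list(mean = cell$prior_mean, var = cell$prior_var))
      else NULL
      priors <- prior_spec(coef_priors = cp)
    }
    for (r in seq_len(n_rep)) {
      sim <- simulate_series(m, covariates, seed = grid$base_seed + r)
      mc <- mcmc_settings(burn_in = grid$burn_in,
                          iterations = grid$iterations,
                          seed = grid$base_seed + 100000L + r)
      rec <- fit_one(sim, cell$engine, spec, priors, mc)
      k <- k + 1L
      rows[[k]] <- data.frame(cell, replicate = r,
                              beta1_hat = rec$beta1, sd = rec$sd,
                              ok = rec$ok, seed = grid$base_seed + r,
                              row.names = NULL)
    }
    if (progress)
      message(sprintf("cell %d/%d done", i, nrow(cells)))
  }
  records <- do.call(rbind, rows[seq_len(k)])
  rownames(records) <- NULL
  records
}

#' Study 1: noise-by-smoothness recovery grid
#'
#' For every combination of noise multiplier `gamma` and smooth
#' flexibility `df_per_year`, simulates replicate death series from the
#' generative model (one shared covariate draw), fits the frequentist
#' and/or Bayesian GAM, and summarizes the lag-1 coefficient estimates
#' per cell as mean and SD.
#'
#' @param grid a [study_grid()] with `study = 1`.
#' @param model generative [true_model()].
#' @param covariates optional pre-drawn covariate series; by default
#'   drawn once from `grid$covariate_seed`.
#' @param progress print per-cell progress messages?
#' @return list with `records` (one row per cell, replicate and
#'   engine), `summary` (per-cell mean, SD, count, failure flag) and
#'   the `covariates` used.
#' @export
run_study1 <- function(grid = study_grid(1), model = true_model(),
                       covariates = NULL, progress = FALSE) {
  engines <- switch(grid$engine, both = c("freq", "bayes"), grid$engine)
  if (is.null(covariates))
    covariates <- generate_covariates(grid$n_days,
                                      seed = grid$covariate_seed)
  cells <- expand.grid(engine = engines, gamma = grid$gamma,
                       df_per_year = grid$df_per_year,
                       stringsAsFactors = FALSE)
  cells$true_beta1 <- NA_real_
  cells$prior_mean <- NA_real_
  cells$prior_var <- NA_real_
  records <- run_cells(cells, grid, model, covariates, progress)
  list(records = records,
       summary = summarize_records(records,
                                   by = c("engine", "gamma", "df_per_year")),
       covariates = covariates)
}

#' Study 2: sensitivity to the prior mean and variance
#'
#' Fixed truth (`beta1 = 0.0049`), noise `gamma = 0.5` and smooth df 8
#' per year; Bayesian fits with a normal prior on the lag-1 coefficient
#' whose mean sweeps `grid$prior_mean` and whose variance is
#' `prior_var_factor * prior_mean`.
#'
#' @inheritParams run_study1
#' @param grid a [study_grid()] with `study = 2`.
#' @export
run_study2 <- function(grid = study_grid(2), model = true_model(),
                       covariates = NULL, progress = FALSE) {
  model$gamma <- 0.5
  if (is.null(covariates))
    covariates <- generate_covariates(grid$n_days,
                                      seed = grid$covariate_seed)
  cells <- expand.grid(engine = "bayes", gamma = 0.5, df_per_year = 8,
                       prior_mean = grid$prior_mean,
                       prior_var_factor = grid$prior_var_factor,
                       stringsAsFactors = FALSE)
  cells$prior_var <- cells$prior_mean * cells$prior_var_factor
  cells$true_beta1 <- NA_real_
  records <- run_cells(cells, grid, model, covariates, progress)
  list(records = records,
       summary = summarize_records(records,
                                   by = c("prior_mean", "prior_var")),
       covariates = covariates)
}

#' Study 3: sensitivity to the generative truth
#'
#' Sweeps the generative lag-1 coefficient over `grid$true_beta1`
#' (other coefficients unchanged) at `gamma = 0.5`, fitting the
#' Bayesian GAM with a fixed prior mean 0.005 and variance
#' `prior_var_factor * 0.005`, then regresses the per-truth mean
#' posterior means on the truth grid.
#'
#' @inheritParams run_study1
#' @param grid a [study_grid()] with `study = 3`.
#' @param prior_mean fixed prior mean of the lag-1 coefficient.
#' @return as [run_study1()], plus `regression` (see
#'   [recovery_regression()]).
#' @export
run_study3 <- function(grid = study_grid(3), model = true_model(),
                       covariates = NULL, prior_mean = 0.005,
                       progress = FALSE) {
  model$gamma <- 0.5
  if (is.null(covariates))
    covariates <- generate_covariates(grid$n_days,
                                      seed = grid$covariate_seed)
  cells <- expand.grid(engine = "bayes", gamma = 0.5, df_per_year = 8,
                       true_beta1 = grid$true_beta1,
                       prior_var_factor = grid$prior_var_factor,
                       stringsAsFactors = FALSE)
  cells$prior_mean <- prior_mean
  cells$prior_var <- prior_mean * cells$prior_var_factor
  records <- run_cells(cells, grid, model, covariates, progress)
  summary <- summarize_records(records, by = c("true_beta1", "prior_var"))
  means <- summarize_records(records, by = "true_beta1")
  list(records = records, summary = summary,
       regression = recovery_regression(means, means$true_beta1),
       covariates = covariates)
}

#' Summarize replicate estimates per cell
#'
#' Sample mean and SD (n-1 denominator) of the lag-1 estimates per
#' grouping cell; single-replicate cells report SD 0.  Cells where more
#' than 20% of fits failed are flagged.
#'
#' @param records a records data.frame from a study run (needs columns
#'   `beta1_hat`, `ok` and the grouping columns).
#' @param by character vector of grouping column names.
#' @return data.frame with the grouping columns plus `mean`, `sd`,
#'   `n`, `n_failed`, `flagged`.
#' @export
summarize_records <- function(records, by) {
  split_idx <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  parts <- split(records, split_idx)
  out <- do.call(rbind, lapply(parts, function(d) {
    est <- d$beta1_hat[d$ok]
    cbind(d[1, by, drop = FALSE],
          data.frame(mean = mean(est),
                     sd = if (length(est) > 1) stats::sd(est) else 0,
                     n = length(est), n_failed = sum(!d$ok),
                     flagged = sum(!d$ok) > 0.2 * nrow(d)))
  }))
  rownames(out) <- NULL
  if (any(out$flagged))
    warning("some cells had more than 20% failed fits", call. = FALSE)
  out
}

#' Recovery regression of mean estimates on the truth grid
#'
#' Ordinary least-squares regression of the per-truth mean estimates on
#' the generative truth values, plus the Pearson correlation.  Slope
#' near 1 and correlation near 1 indicate accurate, linear parameter
#' recovery across the sweep.
#'
#' @param summary data.frame with a `mean` column (one row per truth
#'   value), e.g. from [summarize_records()].
#' @param truth numeric vector of generative truth values, same length.
#' @return list with `slope`, `intercept`, `r`.
#' @export
recovery_regression <- function(summary, truth) {
  if (length(truth) < 3 || length(unique(truth)) < 3)
    stop("need at least 3 distinct truth values for the recovery ",
         "regression", call. = FALSE)
  fit <- stats::lm(summary$mean ~ truth)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = stats::cor(truth, summary$mean))
}
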