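#' Generative "true model" for daily respiratory mortality
#'
#' Bundles the coefficients of the distributed-lag Poisson model used to
#' generate synthetic daily death series: intercept, log-rate changes per
#' 10 ug/m3 of PM2.5 at lags 1..7, six synoptic-weather-type (SWT)
#' effects (category 1 is the reference and fixed at 0), seven
#' day-of-week effects (day 0 is the reference), a smooth seasonal trend
#' `S(t)`, the standard deviation of log daily deaths `sigma_hat`, and
#' the noise multiplier `gamma` (noise SD is `gamma * sigma_hat`).
#'
#' The defaults are the coefficient estimates from the Shanghai
#' 2012-2014 respiratory-mortality analysis that this package's
#' simulation studies take as generative truth; `sigma_hat = 0.34` and a
#' target mean of 32 deaths/day come from the same data summary.  The
#' default seasonal trend is a winter-peaked annual cycle with a
#' semi-annual harmonic,
#' `S(t) = a1 sin(2 pi t / 365.25) + a2 cos(2 pi t / 365.25) +
#'  a3 sin(4 pi t / 365.25)`,
#' with amplitudes chosen so the variance of the log mean series is
#' close to 0.08 (see the methods vignette).
#'
#' @param beta0 intercept on the log scale.
#' @param beta_lag numeric length-7: lag 1..7 PM2.5 coefficients
#'   (per 10 ug/m3).
#' @param phi_swt numeric length-6 SWT effects; first element must be 0.
#' @param phi_dow numeric length-7 day-of-week effects; first element
#'   (day 0) must be 0.
#' @param seasonal_trend function of the day index returning `S(t)`, or
#'   a numeric length-3 vector `c(a1, a2, a3)` of harmonic amplitudes.
#' @param sigma_hat SD of log daily deaths (> 0).
#' @param gamma noise multiplier (>= 0; 0 means noiseless).
#' @param mean_deaths target mean daily deaths used by
#'   [calibrate_intercept()]; `NULL` to keep `beta0` as given.
#' @return Object of class `"true_model"`.
#' @export
true_model <- function(beta0 = 3.9666423,
                       beta_lag = c(0.0049014, -0.0020338, 0.0024222,
                                    -0.0000745, 0.0004227, 0.0006673,
                                    -0.0004166),
                       phi_swt = c(0, -0.0612972, -0.0780534, -0.0494911,
                                   -0.0085775, -0.0603464),
                       phi_dow = c(0, -0.0094768, 0.0010382, -0.0140684,
                                   -0.0144893, -0.0104156, -0.0186630),
                       seasonal_trend = c(0.10, 0.37, 0.05),
                       sigma_hat = 0.34,
                       gamma = 0.5,
                       mean_deaths = 32) {
  if (length(beta_lag) != 7)
    stop("'beta_lag' must have length 7 (lags 1..7)", call. = FALSE)
  if (length(phi_swt) != 6 || phi_swt[1] != 0)
    stop("'phi_swt' must have length 6 with reference (category 1) = 0",
         call. = FALSE)
  if (length(phi_dow) != 7 || phi_dow[1] != 0)
    stop("'phi_dow' must have length 7 with reference (day 0) = 0",
         call. = FALSE)
  if (sigma_hat <= 0) stop("'sigma_hat' must be > 0", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  if (is.numeric(seasonal_trend)) {
    if (length(seasonal_trend) != 3)
      stop("numeric 'seasonal_trend' must be c(a1, a2, a3)", call. = FALSE)
    a <- seasonal_trend
    seasonal_trend <- function(t) {
      w <- 2 * pi * t / 365.25
      a[1] * sin(w) + a[2] * cos(w) + a[3] * sin(2 * w)
    }
  }
  if (!is.function(seasonal_trend))
    stop("'seasonal_trend' must be a function or length-3 numeric",
         call. = FALSE)
  structure(list(beta0 = beta0, beta_lag = beta_lag, phi_swt = phi_swt,
                 phi_dow = phi_dow, seasonal_trend = seasonal_trend,
                 sigma_hat = sigma_hat, gamma = gamma,
                 mean_deaths = mean_deaths),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat("Generative model: beta0 =", format(x$beta0), " beta_lag1 =",
      format(x$beta_lag[1]), "\n  sigma_hat =", x$sigma_hat,
      " gamma =", x$gamma, " target mean deaths =",
      if (is.null(x$mean_deaths)) "(none)" else x$mean_deaths, "\n")
  invisible(x)
}

# Deterministic first and second moments of the pre-scaling PM2.5 process
# exp(amp * cos(phase) + g), g ~ N(0, sd^2), averaged over one year of
# phases.  Used for affine moment matching.
pm25_raw_moments <- function(seasonal_amp, ar_sd) {
  phase <- cos(2 * pi * (0:364) / 365.25)
  m1 <- mean(exp(seasonal_amp * phase)) * exp(ar_sd^2 / 2)
  m2 <- mean(exp(2 * seasonal_amp * phase)) * exp(2 * ar_sd^2)
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Generate daily covariate series
#'
#' Simulates the covariates of the mortality model for `n_days` days:
#' a right-skewed, autocorrelated, seasonal PM2.5 concentration series
#' moment-matched to a target mean and SD, a seasonally structured
#' 6-level synoptic weather type, and a day-of-week index cycling 0..6.
#' PM2.5 is an exponentiated AR(1) Gaussian process plus a winter-peaked
#' annual cosine, affinely rescaled so that its theoretical mean and SD
#' hit the calibration targets, then truncated below at the calibration
#' minimum.  Seven pre-period days of PM2.5 are generated so that the
#' lag-1..7 design is complete for every output day.
#'
#' @param n_days length of the series (default 1096, three years);
#'   must be at least 8.
#' @param seed RNG seed (required for reproducibility).
#' @param calibration list with elements `pm25_mean`, `pm25_sd`,
#'   `pm25_min` (ug/m3).
#' @param ar1 AR(1) coefficient of the latent Gaussian process.
#' @param pm_seasonal_amp amplitude of the annual cosine on the latent
#'   log scale.
#' @param pm_sigma marginal SD of the latent AR(1) process.
#' @param swt_strength strength of the seasonal tilt of the SWT
#'   multinomial probabilities.
#' @param start_date calendar date of day 1.
#' @return Object of class `"covariate_series"`: list with `n_days`,
#'   day index `t`, `date`, `pm25` (ug/m3), `pm25_history` (the 7
#'   pre-period values, oldest first), `lags` (`n_days` by 7 matrix in
#'   10 ug/m3 units, column l = PM2.5 on day t - l), `swt` (integer
#'   1..6) and `dow` (integer 0..6).
#' @export
generate_covariates <- function(n_days = 1096, seed = 1,
                                calibration = list(pm25_mean = 55.0,
                                                   pm25_sd = 38.6,
                                                   pm25_min = 3.0),
                                ar1 = 0.6,
                                pm_seasonal_amp = 0.30,
                                pm_sigma = 0.60,
                                swt_strength = 1.2,
                                start_date = as.Date("2012-01-01")) {
  if (n_days < 8)
    stop("'n_days' must be at least 8 (lags 1..7 plus one day)",
         call. = FALSE)
  set.seed(seed)
  n_total <- n_days + 7L              # 7 pre-period days for the lags
  t_full <- (-6L):n_days              # day index, history first

  innov_sd <- pm_sigma * sqrt(1 - ar1^2)
  g0 <- stats::rnorm(1, 0, pm_sigma)
  g <- as.numeric(stats::filter(stats::rnorm(n_total, 0, innov_sd),
                                filter = ar1, method = "recursive",
                                init = g0))
  z <- pm_seasonal_amp * cos(2 * pi * t_full / 365.25) + g
  raw <- exp(z)
  mom <- pm25_raw_moments(pm_seasonal_amp, pm_sigma)
  b <- calibration$pm25_sd / mom["sd"]
  a <- calibration$pm25_mean - b * mom["mean"]
  pm_full <- pmax(as.numeric(a + b * raw), calibration$pm25_min)

  pm25 <- pm_full[8:n_total]
  lags <- sapply(1:7, function(l) pm_full[(8:n_total) - l] / 10)
  colnames(lags) <- paste0("lag", 1:7)

  # SWT: categories 1 hot dry, 2 warm humid, 3 cold dry, 4 moderately
  # dry, 5 moderately humid, 6 cold humid; cold types favored in winter
  # (cos phase ~ +1 near t = 0), hot types in summer.
  tday <- 1:n_days
  coldness <- cos(2 * pi * tday / 365.25)
  pref <- c(-1.0, -0.6, 1.0, 0.2, -0.2, 0.8)
  swt <- integer(n_days)
  for (i in seq_len(n_days)) {
    w <- exp(swt_strength * coldness[i] * pref)
    swt[i] <- sample.int(6, 1, prob = w / sum(w))
  }

  structure(list(n_days = n_days, t = tday,
                 date = start_date + (tday - 1L),
                 pm25 = pm25, pm25_history = pm_full[1:7],
                 lags = lags, swt = swt,
                 dow = (tday - 1L) %% 7L, seed = seed),
            class = "covariate_series")
}

#' @export
print.covariate_series <- function(x, ...) {
  cat("Daily covariate series:", x$n_days, "days starting",
      format(x$date[1]), "\n  PM2.5 mean", round(mean(x$pm25), 1),
      "ug/m3, SD", round(stats::sd(x$pm25), 1), "\n")
  invisible(x)
}

#' Linear predictor of the generative model
#'
#' Evaluates `eta_t = beta0 + sum_l beta_l * lag_l(t) + S(t) +
#' phi_swt[swt_t] + phi_dow[dow_t]` for every day of a covariate series.
#' The expected death count is `exp(eta_t)`.  Days with incomplete lag
#' information (possible for series read from file) yield `NA`.
#'
#' @param model a [true_model()].
#' @param covariates a [generate_covariates()] result (or the
#'   `covariates` element of [read_series()]).
#' @return numeric vector of log means, one per day.
#' @export
linear_predictor <- function(model, covariates) {
  stopifnot(inherits(model, "true_model"),
            inherits(covariates, "covariate_series"))
  if (any(!(covariates$swt %in% 1:6)))
    stop("unknown SWT category level (must be 1..6)", call. = FALSE)
  if (any(!(covariates$dow %in% 0:6)))
    stop("unknown day-of-week level (must be 0..6)", call. = FALSE)
  as.numeric(model$beta0 +
    covariates$lags %*% model$beta_lag +
    model$seasonal_trend(covariates$t) +
    model$phi_swt[covariates$swt] +
    model$phi_dow[covariates$dow + 1L])
}

#' Calibrate the intercept to a target mean death count
#'
#' Offsets `beta0` so that the mean of `exp(eta_t)` over the given
#' covariate series equals `model$mean_deaths`.  The uncalibrated
#' intercept was estimated on the original covariates, so reusing it on
#' a fresh synthetic covariate draw would not reproduce the observed
#' mean daily mortality.
#'
#' @inheritParams linear_predictor
#' @return the model with adjusted `beta0`.
#' @export
calibrate_intercept <- function(model, covariates) {
  if (is.null(model$mean_deaths)) return(model)
  eta <- linear_predictor(model, covariates)
  model$beta0 <- model$beta0 + log(model$mean_deaths) - log(mean(exp(eta)))
  model
}

#' Simulate daily deaths by multiplicative lognormal noise
#'
#' Multiplies the mean series by `exp(eps)` with
#' `eps ~ N(0, (gamma * sigma_hat)^2)` i.i.d.  With `gamma = 0` the
#' deaths equal the means bit-exactly.  The continuous response is kept
#' by default (the quasi-Poisson fit is well defined for any positive
#' response); `round_counts = TRUE` rounds to the nearest nonnegative
#' integer.
#'
#' @param mean positive numeric vector of expected daily deaths.
#' @param gamma noise multiplier (>= 0).
#' @param sigma_hat SD of log daily deaths.
#' @param seed RNG seed.
#' @param round_counts round the simulated deaths to integers?
#' @return Object of class `"simulated_series"`: list with `mean`,
#'   `deaths`, the realized noise `epsilon`, `seed`, `gamma`,
#'   `sigma_hat`.
#' @export
simulate_deaths <- function(mean, gamma, sigma_hat = 0.34, seed = 1,
                            round_counts = FALSE) {
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  if (sigma_hat <= 0) stop("'sigma_hat' must be > 0", call. = FALSE)
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("'mean' must be finite and positive elementwise", call. = FALSE)
  set.seed(seed)
  if (gamma == 0) {
    eps <- numeric(length(mean))
    deaths <- mean
  } else {
    eps <- stats::rnorm(length(mean), 0, gamma * sigma_hat)
    deaths <- mean * exp(eps)
  }
  if (round_counts) deaths <- pmax(0, round(deaths))
  structure(list(mean = mean, deaths = deaths, epsilon = eps,
                 seed = seed, gamma = gamma, sigma_hat = sigma_hat),
            class = "simulated_series")
}

#' Generate a complete simulated mortality series
#'
#' Convenience wrapper: calibrates the intercept on the covariate draw
#' (unless disabled in the model), evaluates the linear predictor and
#' draws the noisy death series.
#'
#' @inheritParams linear_predictor
#' @param seed RNG seed for the noise draws (the covariate draw has its
#'   own seed).
#' @param round_counts round deaths to integers?
#' @return list with `covariates`, `model` (intercept-calibrated),
#'   `mean`, `deaths`, `epsilon`, `seed`.
#' @export
simulate_series <- function(model, covariates, seed = 1,
                            round_counts = FALSE) {
  model <- calibrate_intercept(model, covariates)
  mu <- exp(linear_predictor(model, covariates))
  sim <- simulate_deaths(mu, model$gamma, model$sigma_hat, seed = seed,
                         round_counts = round_counts)
  list(covariates = covariates, model = model, mean = sim$mean,
       deaths = sim$deaths, epsilon = sim$epsilon, seed = seed)
}
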