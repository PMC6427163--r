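test_that("model and generator inputs are validated", {
  expect_error(true_model(beta_lag = rep(0, 6)), "length 7")
  expect_error(true_model(phi_swt = c(0.1, rep(0, 5))), "reference")
  expect_error(true_model(gamma = -0.1), "gamma")
  expect_error(generate_covariates(n_days = 6), "at least 8")
  expect_error(simulate_deaths(rep(10, 5), gamma = -0.5), "gamma")
  expect_error(simulate_deaths(c(10, -1), gamma = 0.5), "positive")
})

test_that("lag columns are exact shifts of the PM2.5 series", {
  cov <- generate_covariates(300, seed = 4)
  for (l in 2:7) {
    t_ok <- l:300
    expect_identical(cov$lags[t_ok, l], cov$lags[t_ok - l + 1, 1])
  }
  # lag 1 against the published series itself
  expect_identical(cov$lags[2:300, 1], cov$pm25[1:299] / 10)
})

test_that("PM2.5 marginal moments hit the calibration targets", {
  cov <- generate_covariates(100000, seed = 2)
  expect_gt(mean(cov$pm25), 52.3); expect_lt(mean(cov$pm25), 57.8)
  expect_gt(sd(cov$pm25), 36.7); expect_lt(sd(cov$pm25), 40.5)
  expect_true(all(cov$pm25 >= 3.0))
  # seasonal and autocorrelated
  expect_gt(cor(cov$pm25[-1], cov$pm25[-length(cov$pm25)]), 0.3)
  win <- cos(2 * pi * cov$t / 365.25) > 0.7   # winter days
  expect_gt(mean(cov$pm25[win]), mean(cov$pm25[!win]))
})

test_that("moment-matching constants agree with a brute-force MC oracle", {
  # the affine calibration uses closed-form lognormal moments; check
  # them against a large Monte-Carlo simulation of the latent process
  mom <- bgamsim:::pm25_raw_moments(0.30, 0.60)
  set.seed(9)
  n <- 1e6
  g <- as.numeric(stats::filter(rnorm(n, 0, 0.6 * sqrt(1 - 0.36)),
                                filter = 0.6, method = "recursive",
                                init = rnorm(1, 0, 0.6)))
  raw <- exp(0.30 * cos(2 * pi * seq_len(n) / 365.25) + g)
  expect_equal(mean(raw), unname(mom["mean"]), tolerance = 0.01)
  expect_equal(sd(raw), unname(mom["sd"]), tolerance = 0.02)
})

test_that("linear predictor reproduces the generative coefficients", {
  m <- true_model(seasonal_trend = function(t) rep(0, length(t)),
                  mean_deaths = NULL)
  cov0 <- toy_covariates(rep(0, 20))       # all reference, zero PM2.5
  expect_equal(exp(linear_predictor(m, cov0)), rep(exp(3.9666423), 20))
  # one unit (10 ug/m3) of lag-1 PM2.5 multiplies the mean by exp(beta1)
  cov1 <- cov0; cov1$lags[5, 1] <- cov1$lags[5, 1] + 1
  r <- exp(linear_predictor(m, cov1)) / exp(linear_predictor(m, cov0))
  expect_equal(r[5], exp(0.0049014), tolerance = 1e-12)
  expect_equal(r[-5], rep(1, 19))
  # unknown category levels are a domain error
  cov_bad <- cov0; cov_bad$swt[3] <- 9L
  expect_error(linear_predictor(m, cov_bad), "SWT")
})

test_that("vectorized linear predictor matches per-term summation oracle", {
  set.seed(21)
  cov <- generate_covariates(150, seed = 3)
  m <- true_model(beta0 = rnorm(1), beta_lag = rnorm(7, 0, 0.01),
                  phi_swt = c(0, rnorm(5, 0, 0.1)),
                  phi_dow = c(0, rnorm(6, 0, 0.02)),
                  seasonal_trend = c(0.2, 0.3, 0.1), mean_deaths = NULL)
  eta <- linear_predictor(m, cov)
  oracle <- numeric(150)
  for (t in 1:150) {
    s <- m$beta0
    for (l in 1:7) s <- s + m$beta_lag[l] * cov$lags[t, l]
    w <- 2 * pi * t / 365.25
    s <- s + 0.2 * sin(w) + 0.3 * cos(w) + 0.1 * sin(2 * w)
    s <- s + m$phi_swt[cov$swt[t]] + m$phi_dow[cov$dow[t] + 1]
    oracle[t] <- s
  }
  expect_equal(eta, oracle, tolerance = 1e-12)
})

test_that("gamma = 0 reproduces the mean series bit-exactly", {
  mu <- exp(rnorm(50, 3.4, 0.2))
  sim <- simulate_deaths(mu, gamma = 0, seed = 8)
  expect_identical(sim$deaths, mu)
  expect_identical(sim$epsilon, numeric(50))
})

test_that("expected deaths carry the lognormal mean factor exp(sigma^2/2)", {
  mu <- rep(20, 1e6)
  gamma <- 0.6; sh <- 0.34
  sim <- simulate_deaths(mu, gamma = gamma, sigma_hat = sh, seed = 12)
  s2 <- (gamma * sh)^2
  theo <- 20 * exp(s2 / 2)
  mc_se <- 20 * sqrt((exp(s2) - 1) * exp(s2)) / sqrt(1e6)
  expect_lt(abs(mean(sim$deaths) - theo), 4 * mc_se)
})

test_that("calibrated generator hits the observed mortality scale", {
  cov <- generate_covariates(1096, seed = 101)
  m <- true_model()
  means <- sapply(1:10, function(r)
    mean(simulate_series(m, cov, seed = 100 + r)$deaths))
  expect_lt(abs(mean(means) - 32), 2)
  sds <- sapply(1:10, function(r)
    sd(simulate_series(m, cov, seed = 100 + r)$deaths))
  expect_gt(mean(sds), 8); expect_lt(mean(sds), 14)
})

test_that("sample SD of deaths is nondecreasing in gamma", {
  cov <- generate_covariates(1096, seed = 101)
  m <- calibrate_intercept(true_model(), cov)
  mu <- exp(linear_predictor(m, cov))
  gammas <- seq(0.1, 1.0, by = 0.1)
  mean_sd <- sapply(gammas, function(g)
    mean(sapply(1:20, function(r)
      sd(simulate_deaths(mu, g, seed = 500 + r)$deaths))))
  expect_true(all(diff(mean_sd) >= 0))
})

test_that("simulation is reproducible from its seeds", {
  a <- generate_covariates(100, seed = 77)
  b <- generate_covariates(100, seed = 77)
  expect_identical(a$pm25, b$pm25)
  expect_identical(a$swt, b$swt)
  m <- true_model()
  s1 <- simulate_series(m, a, seed = 5)
  s2 <- simulate_series(m, b, seed = 5)
  expect_identical(s1$deaths, s2$deaths)
})
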