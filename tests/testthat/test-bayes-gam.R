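test_that("log posterior matches a term-by-term summation oracle", {
  # 5-day toy dataset, tiny design with named columns
  y <- c(3, 5, 2, 4, 6)
  X <- cbind("(Intercept)" = 1, lag1 = c(0.1, 0.5, 0.2, 0.8, 0.4),
             s1 = c(1, 0, 0, 1, 0), s2 = c(0, 1, 1, 0, 1))
  K <- difference_penalty(2, order = 1)$K
  beta <- c(1.2, 0.3, 0.2, -0.1)
  tau2 <- 0.7
  cp <- list(lag1 = list(mean = 0.1, var = 0.5))
  lp <- log_posterior(beta, y, X, sm_idx = 3:4, K = K, tau2 = tau2,
                      coef_priors = cp)
  oracle <- 0
  for (t in 1:5) {
    eta <- sum(X[t, ] * beta)
    oracle <- oracle + y[t] * eta - exp(eta)
  }
  bs <- beta[3:4]
  oracle <- oracle - (bs[2] - bs[1])^2 / (2 * tau2)
  oracle <- oracle - (beta[2] - 0.1)^2 / (2 * 0.5)
  expect_equal(lp, oracle, tolerance = 1e-12)
  expect_error(log_posterior(beta[1:3], y, X), "dimension")
})

test_that("flat priors and infinite tau2 reduce to the pure likelihood", {
  set.seed(51)
  y <- rpois(10, 5)
  X <- cbind("(Intercept)" = 1, x = rnorm(10), s1 = rnorm(10), s2 = rnorm(10))
  K <- difference_penalty(2, order = 1)$K
  b1 <- rnorm(4); b2 <- rnorm(4)
  d_post <- log_posterior(b1, y, X, 3:4, K, tau2 = Inf) -
    log_posterior(b2, y, X, 3:4, K, tau2 = Inf)
  d_lik <- (sum(y * (X %*% b1)) - sum(exp(X %*% b1))) -
    (sum(y * (X %*% b2)) - sum(exp(X %*% b2)))
  expect_equal(d_post, d_lik, tolerance = 1e-10)
})

test_that("normal prior contributes the Gaussian quadratic form", {
  # zero design column: likelihood contribution is constant, so the
  # difference isolates the prior term
  y <- 2; X <- cbind(lag1 = 0)
  mu <- 0.005; V <- 0.002; s <- 0.013
  d <- log_posterior(mu, y, X, coef_priors = list(lag1 = list(mean = mu, var = V))) -
    log_posterior(mu + s, y, X, coef_priors = list(lag1 = list(mean = mu, var = V)))
  expect_equal(d, s^2 / (2 * V), tolerance = 1e-12)
})

test_that("random-walk Metropolis recovers a conjugate Gaussian posterior", {
  # Gaussian likelihood with known variance + normal prior: posterior
  # is available in closed form
  set.seed(61)
  yobs <- rnorm(20, 1.5, 1)
  prior_m <- 0; prior_v <- 1
  post_v <- 1 / (1 / prior_v + 20 / 1)
  post_m <- post_v * (prior_m / prior_v + sum(yobs) / 1)
  lt <- function(th) -sum((yobs - th)^2) / 2 - (th - prior_m)^2 / (2 * prior_v)
  th <- 0; lp <- lt(th)
  chain <- numeric(8000)
  for (i in seq_along(chain)) {
    st <- bgamsim:::rw_step(th, lp, lt, matrix(1), 2.4 * sqrt(post_v))
    th <- st$state; lp <- st$lp
    chain[i] <- th
  }
  chain <- chain[-(1:500)]
  se <- batch_se(chain)
  expect_lt(abs(mean(chain) - post_m), 3 * se)
  expect_equal(sd(chain), sqrt(post_v), tolerance = 0.1)
})

test_that("posterior mean matches dense quadrature on a reduced model", {
  # intercept + lag1 only, flat priors: 2-parameter posterior
  # integrable on a grid
  set.seed(71)
  x <- rnorm(200, 5, 2)
  cov <- toy_covariates(x * 10)   # lag1 column = lagged x
  m <- true_model(beta0 = 2.5, beta_lag = c(0.08, rep(0, 6)),
                  phi_swt = rep(0, 6), phi_dow = rep(0, 7),
                  seasonal_trend = function(t) rep(0, length(t)),
                  gamma = 0.4, mean_deaths = NULL)
  sim <- simulate_series(m, cov, seed = 72)
  fit <- fit_bgam(sim, gam_spec(df_per_year = NULL, lags = 1),
                  prior_spec(),
                  mcmc_settings(burn_in = 2000, iterations = 20000,
                                seed = 73))
  X <- fit$mode_fit$design$X
  y <- fit$mode_fit$design$y
  mle <- fit$mode_fit$coefficients
  ses <- fit$mode_fit$se / sqrt(fit$mode_fit$dispersion)
  g0 <- seq(mle[1] - 6 * ses[1], mle[1] + 6 * ses[1], length.out = 251)
  g1 <- seq(mle[2] - 6 * ses[2], mle[2] + 6 * ses[2], length.out = 251)
  ll <- outer(g0, g1, Vectorize(function(b0, b1)
    sum(y * (b0 + b1 * X[, 2])) - sum(exp(b0 + b1 * X[, 2]))))
  w <- exp(ll - max(ll))
  quad_mean <- sum(w * matrix(g1, 251, 251, byrow = TRUE)) / sum(w)
  mcmc_mean <- fit$summary$mean[fit$summary$parameter == "lag1"]
  expect_equal(mcmc_mean, quad_mean, tolerance = 0.02)
})

test_that("posterior summaries follow their definitions", {
  const <- matrix(3.2, 100, 1, dimnames = list(NULL, "a"))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 3.2); expect_equal(s$sd, 0)
  draws <- matrix(1:100, 100, 1, dimnames = list(NULL, "b"))
  s <- summarize_posterior(draws)
  x <- sort(1:100)                       # sort oracle, type-7 interpolation
  lo_pos <- 1 + 0.025 * 99; hi_pos <- 1 + 0.975 * 99
  lo <- x[floor(lo_pos)] + (lo_pos - floor(lo_pos)) *
    (x[ceiling(lo_pos)] - x[floor(lo_pos)])
  hi <- x[floor(hi_pos)] + (hi_pos - floor(hi_pos)) *
    (x[ceiling(hi_pos)] - x[floor(hi_pos)])
  expect_equal(c(s$lower, s$upper), c(lo, hi))
  expect_lte(s$lower, s$upper)
})

test_that("flat-prior posterior concentrates at the penalized MLE", {
  cov <- generate_covariates(1096, seed = 101)
  sim <- simulate_series(true_model(), cov, seed = 1003)
  fit <- fit_bgam(sim, gam_spec(df_per_year = 8), prior_spec(),
                  mcmc_settings(seed = 99))
  s <- fit$summary[fit$summary$parameter == "lag1", ]
  freq <- fit_fgam(sim, gam_spec(df_per_year = 8))
  expect_lt(abs(s$mean - coef(freq)["lag1"]), s$sd)
  expect_lt(s$rhat, 1.1)
  expect_true(all(fit$acceptance > 0 & fit$acceptance < 1))
  expect_equal(nrow(fit$draws), 2000)
  # credible interval bounds ordered for every parameter
  expect_true(all(fit$summary$lower <= fit$summary$upper))
})

test_that("hyperprior mode samples tau2 and stays near the fixed-df fit", {
  cov <- generate_covariates(400, seed = 81)
  sim <- simulate_series(true_model(), cov, seed = 82)
  fit <- fit_bgam(sim, gam_spec(df_per_year = 6),
                  prior_spec(tau2 = "hyper"),
                  mcmc_settings(burn_in = 300, iterations = 600, seed = 83))
  expect_equal(length(fit$tau2_draws), 600)
  expect_true(all(fit$tau2_draws > 0))
  fixed <- fit_bgam(sim, gam_spec(df_per_year = 6), prior_spec(),
                    mcmc_settings(burn_in = 300, iterations = 600,
                                  seed = 83))
  a <- fit$summary$mean[fit$summary$parameter == "lag1"]
  b <- fixed$summary$mean[fixed$summary$parameter == "lag1"]
  # the two smoothness treatments pick different effective df, so they
  # need only agree to the scale of the estimate's SE at this n
  expect_lt(abs(a - b), 0.005)
})

test_that("chains are reproducible from the seed", {
  cov <- generate_covariates(250, seed = 91)
  sim <- simulate_series(true_model(), cov, seed = 92)
  ms <- mcmc_settings(burn_in = 100, iterations = 200, seed = 7)
  f1 <- fit_bgam(sim, gam_spec(df_per_year = 4), prior_spec(), ms)
  f2 <- fit_bgam(sim, gam_spec(df_per_year = 4), prior_spec(), ms)
  expect_identical(f1$draws, f2$draws)
})

test_that("a vague normal prior reproduces the flat-prior fit", {
  cov <- generate_covariates(500, seed = 95)
  sim <- simulate_series(true_model(), cov, seed = 96)
  ms <- mcmc_settings(burn_in = 400, iterations = 800, seed = 97)
  flat <- fit_bgam(sim, gam_spec(df_per_year = 6), prior_spec(), ms)
  vague <- fit_bgam(sim, gam_spec(df_per_year = 6),
                    prior_spec(coef_priors = list(
                      lag1 = list(mean = 0.005, var = 1e6))), ms)
  a <- flat$summary$mean[flat$summary$parameter == "lag1"]
  b <- vague$summary$mean[vague$summary$parameter == "lag1"]
  expect_lt(abs(a - b), 0.0015)
})

test_that("invalid priors and settings are rejected", {
  expect_error(prior_spec(coef_priors = list(lag1 = list(mean = 1, var = -1))),
               "var")
  expect_error(prior_spec(rw_order = 3), "rw_order")
  expect_error(mcmc_settings(burn_in = 0), "positive")
  cov <- generate_covariates(100, seed = 1)
  sim <- simulate_series(true_model(), cov, seed = 2)
  expect_error(fit_bgam(sim, gam_spec(df_per_year = 4),
                        prior_spec(coef_priors = list(
                          nosuch = list(mean = 0, var = 1))),
                        mcmc_settings(burn_in = 10, iterations = 10)),
               "unknown coefficient")
})
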