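#' Specification of the distributed-lag GAM
#'
#' Collects the model settings shared by the frequentist and Bayesian
#' engines: which PM2.5 lags enter linearly, the target effective
#' degrees of freedom (edf) per year for the seasonal smooth, the
#' B-spline settings, and dispersion handling.
#'
#' Smoothness is controlled by tuning the penalty weight `lambda` so
#' that the smooth's edf (trace of its block of the influence matrix)
#' hits `df_per_year` times the series length in years; the basis is
#' kept richer than the target so the same construction covers the
#' whole 1-20 df/year range.  `lambda = 0` (regression-spline mode) is
#' obtained by asking for the maximal df.
#'
#' @param df_per_year target edf per year for the seasonal smooth;
#'   `NULL` drops the smooth entirely (plain GLM).
#' @param lags integer subset of 1..7.
#' @param degree B-spline degree.
#' @param segments_per_year knot segments per year; default grows with
#'   the df target so the basis always spans it.
#' @param penalty_order difference-penalty / random-walk order (1 or 2).
#' @param quasi scale standard errors by the Pearson dispersion
#'   estimate (quasi-Poisson)?
#' @param lambda optional fixed penalty weight, bypassing the df dial.
#' @param max_iter,tol penalized-IRLS iteration cap and relative
#'   deviance tolerance.
#' @return object of class `"gam_spec"`.
#' @export
gam_spec <- function(df_per_year = 10, lags = 1:7, degree = 3,
                     segments_per_year = NULL, penalty_order = 2,
                     quasi = TRUE, lambda = NULL, max_iter = 100,
                     tol = 1e-8) {
  if (!is.null(df_per_year) && df_per_year < 1)
    stop("'df_per_year' must be >= 1", call. = FALSE)
  if (!all(lags %in% 1:7)) stop("'lags' must be within 1..7", call. = FALSE)
  if (is.null(segments_per_year))
    segments_per_year <- if (is.null(df_per_year)) 8
                         else max(8, ceiling(df_per_year) + 4)
  structure(list(df_per_year = df_per_year, lags = as.integer(lags),
                 degree = degree, segments_per_year = segments_per_year,
                 penalty_order = penalty_order, quasi = quasi,
                 lambda = lambda, max_iter = max_iter, tol = tol),
            class = "gam_spec")
}

# Penalized IRLS for the Poisson log link with fixed penalty weight.
pirls <- function(X, y, S, lambda, max_iter = 100, tol = 1e-8,
                  beta0 = NULL) {
  mu <- pmax(y, 1e-3)
  eta <- log(mu)
  if (!is.null(beta0)) {
    eta <- as.numeric(X %*% beta0)
    mu <- exp(eta)
  }
  dev <- poisson_deviance(y, mu)
  beta <- beta0
  for (it in seq_len(max_iter)) {
    w <- mu
    z <- eta + (y - mu) / mu
    Hp <- crossprod(X * sqrt(w)) + lambda * S
    ch <- tryCatch(chol(Hp), error = function(e)
      stop("rank-deficient penalized system (collinear design?)",
           call. = FALSE))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * z)))
    eta <- as.numeric(X %*% beta)
    if (any(eta > 30))
      stop("divergent linear predictor in penalized IRLS", call. = FALSE)
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu)
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    dev <- dev_new
    if (done)
      return(list(beta = as.numeric(beta), eta = eta, mu = mu, w = mu,
                  deviance = dev, iterations = it, converged = TRUE))
  }
  stop("penalized IRLS failed to converge in ", max_iter, " iterations",
       call. = FALSE)
}

#' Map a target effective degrees of freedom to a penalty weight
#'
#' Finds `lambda` such that the smooth's effective degrees of freedom,
#' the trace of its block of the influence matrix
#' `(X'WX + lambda S)^{-1} X'WX` at the supplied working weights,
#' equals `target_df`.  Because the unpenalized (parametric) columns of
#' `S` are zero, their diagonal influence entries are exactly 1, so the
#' smooth edf is the total trace minus the parametric count; the trace
#' reduces to `sum(1 / (1 + lambda * s_i))` over the generalized
#' eigenvalues `s_i` of `(S, X'WX)`, which is continuous and strictly
#' decreasing in `lambda`, and the root is found by monotone bisection
#' on `log(lambda)`.
#'
#' @param X full design matrix (parametric columns then smooth columns).
#' @param S penalty matrix embedded at the smooth block (zero
#'   elsewhere).
#' @param weights positive working weights (for Poisson IRLS, the
#'   fitted means).
#' @param target_df requested smooth edf; must lie in
#'   (penalty null-space dimension, number of smooth columns].
#' @param n_par number of unpenalized parametric columns.
#' @param tol edf tolerance of the bisection (default 0.01).
#' @return the penalty weight `lambda` (0 when the target is the
#'   unpenalized maximum).
#' @export
df_to_lambda <- function(X, S, weights, target_df, n_par, tol = 0.01) {
  p <- ncol(X)
  H <- crossprod(X * sqrt(weights))
  R <- tryCatch(chol(H), error = function(e)
    stop("design not full rank at these weights", call. = FALSE))
  # M0 = R^{-T} S R^{-1}; its eigenvalues are the generalized
  # eigenvalues of (S, H)
  C1 <- forwardsolve(t(R), S)
  M0 <- t(forwardsolve(t(R), t(C1)))
  s <- eigen((M0 + t(M0)) / 2, symmetric = TRUE, only.values = TRUE)$values
  s <- pmax(s, 0)
  edf_of <- function(lambda) sum(1 / (1 + lambda * s)) - n_par
  edf_max <- p - n_par                      # lambda = 0
  edf_min <- sum(s < 1e-12) - n_par         # lambda -> Inf
  if (target_df >= edf_max - tol) return(0)
  if (target_df <= edf_min + tol)
    stop("target edf ", target_df, " unattainable: penalized minimum is ",
         round(edf_min, 2), call. = FALSE)
  lo <- -25; hi <- 30                        # log lambda bracket
  if (edf_of(exp(lo)) < target_df || edf_of(exp(hi)) > target_df)
    stop("target edf outside the bracketed lambda range", call. = FALSE)
  repeat {
    mid <- (lo + hi) / 2
    e <- edf_of(exp(mid))
    if (abs(e - target_df) < tol || hi - lo < 1e-12) return(exp(mid))
    if (e > target_df) lo <- mid else hi <- mid
  }
}

# total and smooth edf plus covariance at a converged fit
edf_and_cov <- function(X, S, lambda, w, n_par) {
  H <- crossprod(X * sqrt(w))
  Hp <- H + lambda * S
  ch <- chol(Hp)
  Hp_inv <- chol2inv(ch)
  diagF <- 1 - lambda * rowSums(Hp_inv * S)  # diag of (Hp^-1 H)
  V_sand <- Hp_inv %*% H %*% Hp_inv
  list(edf = diagF, edf_total = sum(diagF),
       edf_smooth = sum(diagF) - n_par, Hp_inv = Hp_inv, V = V_sand,
       H = H)
}

#' Fit the distributed-lag Poisson GAM by penalized IRLS
#'
#' Maximizes the (quasi-)Poisson log-likelihood minus
#' `lambda/2 * t(beta_s) S beta_s` for the model
#' `log E(Y_t) = beta0 + sum_l beta_l lag_l(t) + S(t) + phi_swt + phi_dow`,
#' with `lambda` tuned so the seasonal smooth attains the requested
#' effective degrees of freedom.  Days with incomplete lag information
#' are dropped (complete-case).  Standard errors come from the
#' sandwich `(X'WX + lambda S)^{-1} X'WX (X'WX + lambda S)^{-1}`,
#' scaled by the Pearson dispersion when `spec$quasi` is `TRUE`.
#'
#' @param data a list with elements `covariates` (a
#'   [generate_covariates()] / [read_series()] series) and `deaths`
#'   (positive numeric), e.g. the result of [simulate_series()].
#' @param spec a [gam_spec()].
#' @return Object of class `"fgam_fit"`: named `coefficients` and `se`,
#'   `vcov`, `lambda`, `edf_smooth`, `edf_total`, `dispersion`,
#'   `deviance`, `iterations`, `converged`, plus the internal `design`
#'   (reused by the Bayesian engine) and fitted `mu`.
#' @export
fit_fgam <- function(data, spec = gam_spec()) {
  stopifnot(inherits(spec, "gam_spec"))
  cov <- data$covariates
  years <- cov$n_days / 365.25
  with_smooth <- !is.null(spec$df_per_year)
  n_seg <- if (with_smooth)
    max(ceiling(spec$segments_per_year * years), spec$degree + 2) else NULL
  des <- build_design(cov, data$deaths, lags = spec$lags,
                      degree = spec$degree, n_segments = n_seg,
                      penalty_order = spec$penalty_order,
                      with_smooth = with_smooth)
  X <- des$X; y <- des$y; S <- des$S

  if (!with_smooth) {
    fit <- pirls(X, y, S, 0, spec$max_iter, spec$tol)
    lambda <- 0
    target <- NULL
  } else if (!is.null(spec$lambda)) {
    lambda <- spec$lambda
    fit <- pirls(X, y, S, lambda, spec$max_iter, spec$tol)
    target <- NULL
  } else {
    target <- spec$df_per_year * years
    if (target > length(des$sm_idx))
      stop("df target exceeds the spline basis dimension; increase ",
           "'segments_per_year'", call. = FALSE)
    lambda <- 1
    fit <- pirls(X, y, S, lambda, spec$max_iter, spec$tol)
    for (k in 1:10) {
      lambda_new <- df_to_lambda(X, S, fit$w, target, des$p_par)
      fit <- pirls(X, y, S, lambda_new, spec$max_iter, spec$tol,
                   beta0 = fit$beta)
      lambda <- lambda_new
      ec <- edf_and_cov(X, S, lambda, fit$w, des$p_par)
      if (abs(ec$edf_smooth - target) < 0.01) break
    }
  }
  ec <- edf_and_cov(X, S, lambda, fit$w, des$p_par)
  n <- length(y)
  pearson <- sum((y - fit$mu)^2 / fit$mu)
  dispersion <- if (spec$quasi) pearson / (n - ec$edf_total) else 1
  V <- dispersion * ec$V
  se <- sqrt(pmax(diag(V), 0))
  names(fit$beta) <- names(se) <- des$names

  structure(list(coefficients = fit$beta, se = se, vcov = V,
                 lambda = lambda, edf = ec$edf,
                 edf_smooth = ec$edf_smooth, edf_total = ec$edf_total,
                 df_target = target, dispersion = dispersion,
                 deviance = fit$deviance, iterations = fit$iterations,
                 converged = fit$converged, mu = fit$mu, eta = fit$eta,
                 design = des, spec = spec, n = n),
            class = "fgam_fit")
}

#' @export
coef.fgam_fit <- function(object, ...) object$coefficients

#' @export
vcov.fgam_fit <- function(object, ...) object$vcov

#' @export
print.fgam_fit <- function(x, ...) {
  cat("Penalized Poisson GAM (", x$n, " days)\n", sep = "")
  cat("  lag1 coefficient:", format(x$coefficients["lag1"]),
      " SE:", format(x$se["lag1"]), "\n")
  cat("  smooth edf:", round(x$edf_smooth, 2),
      " lambda:", format(x$lambda, digits = 4),
      " dispersion:", round(x$dispersion, 3), "\n")
  invisible(x)
}
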