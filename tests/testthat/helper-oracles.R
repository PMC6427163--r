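# Independent oracles used by the tests.  These are deliberately naive
# (loops, recursions, dense grids) and share no code with the package.

# Cox-de Boor recursion for a single B-spline basis function
cdb_one <- function(x, knots, m, degree) {
  if (degree == 0)
    return(as.numeric(knots[m] <= x & x < knots[m + 1]))
  d1 <- knots[m + degree] - knots[m]
  d2 <- knots[m + degree + 1] - knots[m + 1]
  a <- if (d1 > 0) (x - knots[m]) / d1 * cdb_one(x, knots, m, degree - 1) else 0
  b <- if (d2 > 0) (knots[m + degree + 1] - x) / d2 *
    cdb_one(x, knots, m + 1, degree - 1) else 0
  a + b
}

# full basis matrix by recursion; valid for x strictly inside the domain
cdb_basis <- function(x, knots, degree) {
  M <- length(knots) - degree - 1
  sapply(seq_len(M), function(m) cdb_one(x, knots, m, degree))
}

# Newton-Raphson Poisson GLM with log link
newton_poisson <- function(X, y, tol = 1e-12, max_iter = 50) {
  beta <- qr.solve(X, log(pmax(y, 0.5)))
  for (i in seq_len(max_iter)) {
    mu <- exp(as.numeric(X %*% beta))
    g <- crossprod(X, y - mu)
    H <- crossprod(X * sqrt(mu))
    beta <- beta + solve(H, g)
    if (max(abs(g)) < tol) break
  }
  as.numeric(beta)
}

# batch-means Monte Carlo standard error of a chain mean
batch_se <- function(x, n_batch = 25) {
  n <- floor(length(x) / n_batch) * n_batch
  bm <- colMeans(matrix(x[1:n], nrow = n / n_batch))
  stats::sd(bm) / sqrt(n_batch)
}

# hand-built covariate series for toy designs (constant swt/dow unless
# given); lag columns built from the series with a flat pre-period
toy_covariates <- function(pm25, swt = NULL, dow = NULL) {
  n <- length(pm25)
  full <- c(rep(pm25[1], 7), pm25)
  lags <- sapply(1:7, function(l) full[(8:(n + 7)) - l] / 10)
  colnames(lags) <- paste0("lag", 1:7)
  structure(list(n_days = n, t = seq_len(n),
                 date = as.Date("2012-01-01") + seq_len(n) - 1,
                 pm25 = pm25, pm25_history = full[1:7], lags = lags,
                 swt = swt %||% rep(1L, n), dow = dow %||% rep(0L, n),
                 seed = NA),
            class = "covariate_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
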