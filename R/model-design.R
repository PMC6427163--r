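# Internal: assemble the model design shared by the frequentist and
# Bayesian engines.
#
# Parametric block: intercept, PM2.5 lags 1..7 (10 ug/m3 units), SWT
# dummies (first observed level = reference), DOW dummies (day 0 =
# reference).  Smooth block: B-spline basis in the day index under a
# sum-to-zero constraint on the fitted smooth (so the intercept stays
# estimable), with the matching difference penalty reparameterized into
# the constrained space.

build_design <- function(covariates, deaths, lags = 1:7, degree = 3,
                         n_segments = NULL, penalty_order = 2,
                         with_smooth = TRUE) {
  stopifnot(inherits(covariates, "covariate_series"))
  n <- covariates$n_days
  if (length(deaths) != n)
    stop("'deaths' length must match the covariate series", call. = FALSE)
  L <- covariates$lags[, lags, drop = FALSE]
  keep <- stats::complete.cases(L) & is.finite(deaths) & deaths > 0
  n_drop <- sum(!keep)
  L <- L[keep, , drop = FALSE]
  y <- deaths[keep]
  tt <- covariates$t[keep]
  swt <- factor(covariates$swt[keep], levels = sort(unique(covariates$swt[keep])))
  dow <- factor(covariates$dow[keep], levels = sort(unique(covariates$dow[keep])))

  Xp <- cbind("(Intercept)" = 1, L)
  if (nlevels(swt) > 1) {
    Msw <- stats::model.matrix(~swt)[, -1, drop = FALSE]
    colnames(Msw) <- paste0("swt", levels(swt)[-1])
    Xp <- cbind(Xp, Msw)
  }
  if (nlevels(dow) > 1) {
    Mdw <- stats::model.matrix(~dow)[, -1, drop = FALSE]
    colnames(Mdw) <- paste0("dow", levels(dow)[-1])
    Xp <- cbind(Xp, Mdw)
  }
  p_par <- ncol(Xp)

  if (!with_smooth) {
    return(list(X = Xp, y = y, t = tt, S = matrix(0, p_par, p_par),
                par_idx = seq_len(p_par), sm_idx = integer(0),
                p_par = p_par, basis = NULL, Z = NULL, K_con = NULL,
                n_dropped = n_drop, names = colnames(Xp)))
  }

  if (is.null(n_segments)) n_segments <- max(8L, ceiling(n / 90))
  basis <- build_basis(tt, n_segments = n_segments, degree = degree,
                       xlim = c(min(tt) - 0.5, max(tt) + 0.5))
  B <- basis$design
  K <- difference_penalty(basis$M, order = penalty_order)$K
  # sum-to-zero constraint: colSums(B) %*% beta_s = 0
  cvec <- colSums(B)
  qrc <- qr(matrix(cvec, ncol = 1))
  Z <- qr.Q(qrc, complete = TRUE)[, -1, drop = FALSE]
  Bc <- B %*% Z
  Kc <- crossprod(Z, K %*% Z)
  Kc <- (Kc + t(Kc)) / 2
  colnames(Bc) <- paste0("s(t).", seq_len(ncol(Bc)))

  X <- cbind(Xp, Bc)
  p <- ncol(X)
  S <- matrix(0, p, p)
  sm_idx <- (p_par + 1L):p
  S[sm_idx, sm_idx] <- Kc

  list(X = X, y = y, t = tt, S = S, par_idx = seq_len(p_par),
       sm_idx = sm_idx, p_par = p_par, basis = basis, Z = Z, K_con = Kc,
       penalty_order = penalty_order, n_dropped = n_drop,
       names = colnames(X))
}

# Poisson / quasi-Poisson deviance for a positive (possibly
# non-integer) response.
poisson_deviance <- function(y, mu) {
  2 * sum(y * log(y / mu) - (y - mu))
}

poisson_loglik <- function(y, eta) {
  if (any(!is.finite(eta)) || any(eta > 30))
    return(-Inf)  # overflow guard
  sum(y * eta - exp(eta))
}
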