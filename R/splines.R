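#' B-spline basis on equally spaced knots
#'
#' Builds the design matrix of a degree-`degree` B-spline basis with
#' `n_segments` equal-width segments spanning `xlim`.  The basis has
#' `n_segments + degree` columns, each supported on `degree + 2`
#' consecutive knots, and its rows sum to one everywhere on the domain
#' (partition of unity).  This is the basis whose coefficients are
#' regularized by [difference_penalty()] in the frequentist fit and by
#' the equivalent random-walk prior in the Bayesian fit.
#'
#' @param x numeric vector of evaluation points; must lie in `xlim`.
#' @param n_segments number of equal-width knot segments (`d`); the knot
#'   sequence is extended by `degree` replicated-spacing exterior knots
#'   on each side (open uniform construction).
#' @param degree spline degree (default 3, cubic).
#' @param xlim domain `c(min, max)`; defaults to `range(x)`.
#' @return An object of class `"spline_basis"`: a list with the design
#'   matrix `design` (`length(x)` by `M`), the full `knots` sequence,
#'   `degree`, `n_segments`, `M = n_segments + degree` and `xlim`.
#' @examples
#' b <- build_basis(seq(0, 10, by = 0.1), n_segments = 8)
#' range(rowSums(b$design))  # 1 1
#' @export
build_basis <- function(x, n_segments, degree = 3, xlim = range(x)) {
  if (!is.numeric(x) || length(x) == 0)
    stop("'x' must be a nonempty numeric vector", call. = FALSE)
  if (n_segments < 1)
    stop("'n_segments' must be at least 1", call. = FALSE)
  if (degree < 0)
    stop("'degree' must be nonnegative", call. = FALSE)
  if (xlim[2] <= xlim[1])
    stop("'xlim' must be an increasing pair", call. = FALSE)
  if (any(x < xlim[1] | x > xlim[2]))
    stop("'x' outside the knot domain [", xlim[1], ", ", xlim[2], "]",
         call. = FALSE)
  h <- (xlim[2] - xlim[1]) / n_segments
  knots <- seq(xlim[1] - degree * h, xlim[2] + degree * h, by = h)
  # guard against fp drift in seq(): force exact count
  knots <- xlim[1] + h * ((-degree):(n_segments + degree))
  psi <- splines::splineDesign(knots, x, ord = degree + 1)
  structure(
    list(design = psi, knots = knots, degree = degree,
         n_segments = n_segments, M = n_segments + degree, xlim = xlim),
    class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("B-spline basis: degree", x$degree, "with", x$n_segments,
      "segments on [", x$xlim[1], ",", x$xlim[2], "] ->", x$M,
      "basis functions\n")
  invisible(x)
}

#' Difference penalty matrix for P-splines
#'
#' Returns `K = t(D) %*% D` where `D` is the `order`-th order difference
#' operator on `M` spline coefficients.  The quadratic form
#' `t(beta) %*% K %*% beta / (2 * tau2)` is (up to the flat directions)
#' minus the log density of the corresponding random-walk prior: order 1
#' penalizes first differences `beta[m] - beta[m-1]`, order 2 penalizes
#' `beta[m] - 2 beta[m-1] + beta[m-2]`.  `K` is symmetric positive
#' semidefinite with rank `M - order`; its null space is spanned by the
#' polynomial sequences of degree `< order`.
#'
#' @param M number of spline coefficients.
#' @param order difference / random-walk order, 1 or 2.
#' @return Object of class `"penalty_matrix"`: list with `K`, the
#'   difference operator `D`, `order` and `M`.
#' @examples
#' difference_penalty(4, order = 1)$K
#' @export
difference_penalty <- function(M, order = 2) {
  if (!(order %in% c(1L, 2L)))
    stop("unsupported difference order: ", order, " (must be 1 or 2)",
         call. = FALSE)
  if (M <= order)
    stop("'M' must exceed the penalty order", call. = FALSE)
  D <- diff(diag(M), differences = order)
  structure(list(K = crossprod(D), D = D, order = order, M = M),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat("Difference penalty: order", x$order, "on", x$M,
      "coefficients (rank", x$M - x$order, ")\n")
  invisible(x)
}
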