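#' Generic Laplace marginal -2 log-likelihood (reference engine)
#'
#' A small, model-agnostic implementation of the per-subject Laplace
#' approximation used by [marginal_neg2ll()], for arbitrary prediction and
#' error functions.  It serves as the plain-R reference path against which
#' the compiled population-model likelihood is cross-checked, and as a
#' convenient engine for toy models.
#'
#' The joint -2 log density is
#' `sum(log(2 pi s^2) + (y - p)^2 / s^2) + sum(log(2 pi w^2) + eta^2 / w^2)`
#' with `p = pred_fn(eta)` and `s = sd_fn(p)` (error evaluated at the
#' individual prediction, i.e. with eta-epsilon interaction).  The mode is
#' found numerically and the marginal value is
#' `L2(eta_hat) - d log(2 pi) + log det A`, with `A` either the
#' Gauss-Newton matrix `J' S^-1 J + W^-1` or the exact finite-difference
#' Hessian of `L2 / 2`.
#'
#' @param y Observation vector.
#' @param pred_fn Function eta -> predictions (same length as `y`).
#' @param sd_fn Function predictions -> residual SDs.
#' @param omega Vector of random-effect SDs (length = dim of eta).
#' @param eta0 Starting value for the mode search.
#' @param hessian `"gn"` or `"fd"`.
#' @return The -2 log marginal likelihood; the mode is attached as
#'   attribute `eta`.
#' @export
laplace_neg2ll <- function(y, pred_fn, sd_fn, omega, eta0 = NULL,
                           hessian = c("gn", "fd")) {
  hessian <- match.arg(hessian)
  d <- length(omega)
  if (is.null(eta0)) eta0 <- numeric(d)
  l2 <- function(eta) {
    p <- pred_fn(eta)
    s <- sd_fn(p)
    sum(log(2 * pi * s^2) + (y - p)^2 / s^2) +
      sum(log(2 * pi * omega^2) + eta^2 / omega^2)
  }
  opt <- stats::nlminb(eta0, l2, control = list(rel.tol = 1e-12))
  eta <- opt$par
  if (hessian == "fd") {
    A <- 0.5 * stats::optimHess(eta, l2)
  } else {
    p0 <- pred_fn(eta)
    s2 <- sd_fn(p0)^2
    h <- 1e-5
    J <- vapply(seq_len(d), function(j) {
      e <- eta; e[j] <- e[j] + h; pp <- pred_fn(e)
      e[j] <- eta[j] - h; pm <- pred_fn(e)
      (pp - pm) / (2 * h)
    }, numeric(length(y)))
    J <- matrix(J, nrow = length(y))
    A <- crossprod(J, J / s2) + diag(1 / omega^2, d)
  }
  val <- opt$objective - d * log(2 * pi) + 2 * sum(log(diag(chol(A))))
  attr(val, "eta") <- eta
  val
}
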