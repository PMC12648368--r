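# shared fixtures built in code

atv <- pk_defaults("atazanavir")
rtv <- pk_defaults("ritonavir")

# small simulated study dataset reused across tests (2 subjects, full design)
small_dataset <- function(n = 2, seed = 101, err = atv$error) {
  simulate_dataset(sample_cohort(n, seed = seed), ddi_study_design(),
                   atv$structural, atv$variability, err, seed = seed + 1)
}

# multivariate normal log-density (closed-form marginal oracle)
mvtnorm_logd <- function(x, mean, S) {
  ch <- chol(S)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# adaptive 21-node Gauss-Hermite -2 log marginal likelihood for a
# one-dimensional random effect (independent quadrature oracle)
gh_neg2ll_1d <- function(y, pred_fn, sd_fn, omega, nodes = 21) {
  # Golub-Welsch via eigen decomposition of the Jacobi matrix
  i <- seq_len(nodes - 1)
  J <- matrix(0, nodes, nodes)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- (e$vectors[1, ])^2 * sqrt(pi)
  joint <- function(eta) {
    p <- pred_fn(eta)
    s <- sd_fn(p)
    sum(stats::dnorm(y, p, s, log = TRUE)) +
      stats::dnorm(eta, 0, omega, log = TRUE)
  }
  # centre the quadrature at the joint mode with its local curvature
  opt <- stats::optimize(function(e) -joint(e), c(-10, 10))
  mu <- opt$minimum
  h <- 1e-4
  hess <- -(joint(mu + h) - 2 * joint(mu) + joint(mu - h)) / h^2
  tau <- 1 / sqrt(max(hess, 1e-8))
  vals <- vapply(x, function(xi) {
    eta <- mu + sqrt(2) * tau * xi
    joint(eta) + xi^2 + log(sqrt(2) * tau)
  }, numeric(1))
  m <- max(vals)
  -2 * (m + log(sum(w * exp(vals - m))))
}
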