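# Independent oracles and small fixtures shared across the test files.
# Everything here is deliberately written from first principles (no calls
# into the package's own internals) so the dual-route checks stay honest.

# Multivariate normal log-density via determinant + mahalanobis (oracle).
oracle_dmvnorm_log <- function(x, mean, sigma) {
  p <- length(mean)
  -0.5 * (p * log(2 * pi) + determinant(sigma)$modulus[1] +
            stats::mahalanobis(rbind(x), mean, sigma))
}

# [0, Inf)-truncated normal moments by numerical integration (oracle).
oracle_truncnorm_moments <- function(mu, sd) {
  z <- stats::pnorm(0, mu, sd, lower.tail = FALSE)
  m1 <- stats::integrate(function(t) t * stats::dnorm(t, mu, sd), 0, Inf,
                         rel.tol = 1e-12)$value / z
  m2 <- stats::integrate(function(t) t^2 * stats::dnorm(t, mu, sd), 0, Inf,
                         rel.tol = 1e-12)$value / z
  list(m1 = m1, m2 = m2)
}

# Plain Gaussian-mixture EM (oracle for the gmm reduction), full-covariance,
# returning the per-iteration parameter trajectory.
oracle_gmm_em <- function(X, weights, means, covs, n_iter) {
  n <- nrow(X); G <- length(weights)
  traj <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    logd <- sapply(seq_len(G), function(k)
      log(weights[k]) + oracle_dmvnorm_log(X, means[[k]], covs[[k]]))
    mx <- apply(logd, 1, max)
    r <- exp(logd - mx)
    r <- r / rowSums(r)
    nk <- colSums(r)
    weights <- nk / n
    for (k in seq_len(G)) {
      means[[k]] <- colSums(r[, k] * X) / nk[k]
      ctr <- sweep(X, 2, means[[k]])
      covs[[k]] <- crossprod(ctr * r[, k], ctr) / nk[k]
    }
    traj[[it]] <- list(weights = weights, means = means, covs = covs)
  }
  traj
}

# A small, well-behaved two-component skew mixture used by several files.
test_mixture <- function() {
  mixture_params(c(0.4, 0.6),
                 list(c(-2, 0), c(2, 1)),
                 list(diag(2), matrix(c(1, 0.3, 0.3, 1), 2)),
                 list(c(2, 1), c(-1, -2)))
}

# Random valid mixture parameters (moderate separation and skewness).
random_mixture <- function(G = 2, p = 2) {
  locs <- lapply(seq_len(G), function(k) stats::runif(p, -3, 3))
  scales <- lapply(seq_len(G), function(k) {
    A <- matrix(stats::runif(p * p, -0.3, 0.3), p)
    diag(0.5, p) + crossprod(A)
  })
  skews <- lapply(seq_len(G), function(k) stats::runif(p, -2, 2))
  w <- stats::runif(G, 0.5, 1.5)
  mixture_params(w / sum(w), locs, scales, skews)
}
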