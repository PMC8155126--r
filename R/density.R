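#' Multivariate skew-normal log-density
#'
#' Log of the Azzalini density \eqn{f(x) = 2\,\phi_p(x;\xi,\Sigma)\,
#' \Phi(\alpha^T \sigma^{-1}(x-\xi))} with \eqn{\sigma = (\Sigma \odot
#' I_p)^{1/2}}.  With \eqn{\alpha = 0} this is the multivariate normal
#' log-density.  \eqn{\log\Phi} is evaluated on the log scale throughout, so
#' the result stays finite far into the tail.
#'
#' @param x numeric p-vector, or an n x p matrix of row vectors.
#' @param location numeric p-vector \eqn{\xi}.
#' @param scale symmetric, strictly positive-definite p x p matrix.
#' @param skewness numeric p-vector \eqn{\alpha}.
#' @return numeric vector of log-densities (length 1 for a single point).
#' @export
#' @examples
#' msn_logpdf(0, 0, matrix(1), 0)   # log dnorm(0)
#' exp(msn_logpdf(1, 0, matrix(1), 1))  # 2*dnorm(1)*pnorm(1)
msn_logpdf <- function(x, location, scale, skewness) {
  scale <- as.matrix(scale)
  check_pd_scale(scale)
  location <- as.numeric(location)
  skewness <- as.numeric(skewness)
  p <- nrow(scale)
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = p, byrow = TRUE)
  if (ncol(X) != p || length(location) != p || length(skewness) != p)
    stop("dimension mismatch")
  s <- sqrt(diag(scale))
  Z <- (t(X) - location) / s         # p x n standardized residuals
  proj <- drop(crossprod(skewness, Z))
  drop(log(2) + dmvnorm_log(X, location, scale) + log_phi_cdf(proj))
}

#' Skew-normal mixture log-density
#'
#' \eqn{\log \sum_k \pi_k f_{MSN}(x;\xi_k,\Sigma_k,\alpha_k)}, accumulated
#' with a log-sum-exp so that well-scaled inputs never underflow.
#'
#' @param x numeric p-vector or n x p matrix.
#' @param params \code{\link{mixture_params}} object.
#' @return numeric vector of mixture log-densities.
#' @export
msnm_logpdf <- function(x, params) {
  validate_mixture_params(params)
  p <- params$p
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = p, byrow = TRUE)
  lg <- vapply(seq_len(params$G), function(k)
    log(params$weights[k]) + msn_logpdf(X, params$locations[[k]],
                                        params$scales[[k]],
                                        params$skewness[[k]]),
    numeric(nrow(X)))
  if (nrow(X) == 1L) lg <- matrix(lg, nrow = 1L)
  drop(logsumexp_rows(lg))
}

#' Sample from a multivariate skew-normal distribution
#'
#' Uses the stochastic representation \eqn{X = \xi + \eta\tau + W} with
#' \eqn{\tau = |Z_1|} half-normal, \eqn{W \sim N_p(0, \Lambda)},
#' \eqn{\eta = \sigma\delta} and \eqn{\Lambda = \Sigma - \eta\eta^T}.
#' Deterministic given \code{seed}; the caller's RNG state is untouched.
#'
#' @param n number of draws.
#' @param location,scale,skewness parameters as in \code{\link{msn_logpdf}}.
#' @param seed integer seed (\code{NULL} uses the current RNG stream).
#' @return n x p numeric matrix.
#' @export
sample_msn <- function(n, location, scale, skewness, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  aux <- aux_from_primary(location, scale, skewness)
  p <- length(aux$location)
  local_seed(seed, {
    tau <- abs(stats::rnorm(n))
    lam <- aux$lam
    ev <- min_eigval(lam)
    if (ev < 1e-12) lam <- lam + diag(1e-12 - min(ev, 0), p)
    W <- matrix(stats::rnorm(n * p), n, p) %*% chol(lam)
    sweep(W + tau %o% aux$eta, 2, aux$location, "+")
  })
}
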