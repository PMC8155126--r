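#' Construct a skew-normal mixture parameter set
#'
#' Bundles the parameters of a G-component multivariate skew-normal mixture
#' (MSNM): mixing weights \eqn{\pi}, locations \eqn{\xi_k}, scale matrices
#' \eqn{\Sigma_k} and skewness vectors \eqn{\alpha_k}.  The k-th component
#' density is \eqn{2\phi_p(x;\xi_k,\Sigma_k)\Phi(\alpha_k^T\sigma_k^{-1}
#' (x-\xi_k))} with \eqn{\sigma_k = (\Sigma_k \odot I_p)^{1/2}}.
#'
#' @param weights numeric vector of length G on the probability simplex.
#' @param locations list of G numeric p-vectors.
#' @param scales list of G symmetric positive-definite p x p matrices.
#' @param skewness list of G numeric p-vectors; \code{NULL} means all zero
#'   (a Gaussian mixture).
#' @return An object of class \code{"mixture_params"} with fields
#'   \code{G}, \code{p}, \code{weights}, \code{locations}, \code{scales},
#'   \code{skewness}.
#' @export
#' @examples
#' mixture_params(c(.4, .6), list(c(-1, 0), c(1, 0)),
#'                list(diag(2), diag(2)), list(c(2, 0), c(-2, 0)))
mixture_params <- function(weights, locations, scales, skewness = NULL) {
  weights <- as.numeric(weights)
  G <- length(weights)
  if (G < 1L) stop("need at least one component")
  if (!is.list(locations)) locations <- list(as.numeric(locations))
  if (!is.list(scales)) scales <- list(as.matrix(scales))
  locations <- lapply(locations, as.numeric)
  p <- length(locations[[1L]])
  if (is.null(skewness)) skewness <- replicate(G, numeric(p), simplify = FALSE)
  if (!is.list(skewness)) skewness <- list(as.numeric(skewness))
  skewness <- lapply(skewness, as.numeric)
  scales <- lapply(scales, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  obj <- structure(
    list(G = G, p = p, weights = weights, locations = locations,
         scales = scales, skewness = skewness),
    class = "mixture_params")
  validate_mixture_params(obj)
  obj
}

#' Validate a mixture parameter set
#'
#' Checks simplex weights (sum within 1e-12 of one), symmetry and
#' near-positive-semi-definiteness of every scale matrix, and dimension
#' consistency.  Called by every estimation entry point.
#'
#' @param params a \code{"mixture_params"} object.
#' @return \code{params}, invisibly, or an error.
#' @export
validate_mixture_params <- function(params) {
  with(params, {
    if (length(weights) != G) stop("weights length must equal G")
    if (any(weights < 0)) stop("weights must be nonnegative")
    if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
    if (length(locations) != G || length(scales) != G ||
        length(skewness) != G)
      stop("locations, scales and skewness must have G entries")
    for (k in seq_len(G)) {
      if (length(locations[[k]]) != p || length(skewness[[k]]) != p)
        stop("location/skewness dimension mismatch")
      check_square_symmetric(scales[[k]], name = sprintf("scales[[%d]]", k))
      if (nrow(scales[[k]]) != p) stop("scale dimension mismatch")
      if (min_eigval(scales[[k]]) < -1e-10)
        stop(sprintf("scales[[%d]] has a negative eigenvalue", k))
    }
  })
  invisible(params)
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Skew-normal mixture parameters: G = %d components, p = %d\n",
              x$G, x$p))
  cat("weights:", signif(x$weights, 4), "\n")
  for (k in seq_len(x$G)) {
    cat(sprintf("  component %d: xi = (%s), alpha = (%s)\n", k,
                paste(signif(x$locations[[k]], 4), collapse = ", "),
                paste(signif(x$skewness[[k]], 4), collapse = ", ")))
  }
  invisible(x)
}

check_pd_scale <- function(scale, tol = 1e-12) {
  check_square_symmetric(scale, name = "scale")
  if (min_eigval(scale) <= tol)
    stop("scale matrix must be strictly positive definite")
  invisible(TRUE)
}

# Correlation matrix of a scale matrix: sigma^{-1} Sigma sigma^{-1}.
scale_to_corr <- function(scale) {
  s <- sqrt(diag(as.matrix(scale)))
  if (any(s <= 0)) stop("scale matrix has a non-positive diagonal entry")
  sweep(sweep(as.matrix(scale), 1, s, "/"), 2, s, "/")
}

#' Convert skewness alpha to the bounded skewness delta
#'
#' \eqn{\delta = (1 + \alpha^T \bar\Sigma \alpha)^{-1/2} \bar\Sigma \alpha},
#' where \eqn{\bar\Sigma} is the correlation matrix of \code{scale}.  Every
#' entry of the result lies strictly inside (-1, 1).
#'
#' @param skewness numeric p-vector \eqn{\alpha}.
#' @param scale symmetric positive-definite p x p scale matrix.
#' @return numeric p-vector \eqn{\delta}.
#' @export
delta_from_alpha <- function(skewness, scale) {
  scale <- as.matrix(scale)
  check_pd_scale(scale)
  alpha <- as.numeric(skewness)
  if (length(alpha) != nrow(scale)) stop("dimension mismatch")
  corr <- scale_to_corr(scale)
  ca <- drop(corr %*% alpha)
  drop(ca / sqrt(1 + sum(alpha * ca)))
}

#' Convert bounded skewness delta back to alpha
#'
#' Inverse of \code{\link{delta_from_alpha}}:
#' \eqn{\alpha = (1 - \delta^T \bar\Sigma^{-1}\delta)^{-1/2}
#' \bar\Sigma^{-1}\delta}.  Requires \eqn{\delta^T\bar\Sigma^{-1}\delta < 1};
#' callers hitting the boundary after noise must clip first (see
#' \code{\link{repair_component}}).
#'
#' @param delta numeric p-vector with entries in (-1, 1).
#' @param scale symmetric positive-definite p x p scale matrix.
#' @return numeric p-vector \eqn{\alpha}.
#' @export
alpha_from_delta <- function(delta, scale) {
  scale <- as.matrix(scale)
  check_pd_scale(scale)
  delta <- as.numeric(delta)
  if (length(delta) != nrow(scale)) stop("dimension mismatch")
  if (any(abs(delta) >= 1)) stop("all |delta_j| must be < 1")
  corr <- scale_to_corr(scale)
  cid <- solve(corr, delta)
  q <- sum(delta * cid)
  if (q >= 1) stop("delta' corr^{-1} delta must be < 1; clip delta first")
  drop(cid / sqrt(1 - q))
}

#' Auxiliary (conditional) parameterization of one component
#'
#' Computes the reparameterization used by the EM algorithm:
#' \eqn{\sigma = (\Sigma \odot I_p)^{1/2}}, correlation \eqn{\bar\Sigma},
#' \eqn{\delta}, \eqn{\eta = \sigma\delta}, conditional scale
#' \eqn{\Lambda = \Sigma - \eta\eta^T}, \eqn{D_\delta =
#' (I_p - \mathrm{diag}(\delta)^2)^{1/2}}, \eqn{\omega = D_\delta^{-1}\delta}
#' and the full-rank correlation \eqn{\bar\Omega = D_\delta^{-1}\bar\Sigma
#' D_\delta^{-1} - \omega\omega^T}.
#'
#' @param location numeric p-vector \eqn{\xi}.
#' @param scale symmetric positive-definite p x p matrix \eqn{\Sigma}.
#' @param skewness numeric p-vector \eqn{\alpha}.
#' @return list of class \code{"component_aux"} with fields \code{location},
#'   \code{sigma}, \code{corr}, \code{delta}, \code{eta}, \code{lam},
#'   \code{d_delta}, \code{omega}, \code{omega_bar}.
#' @export
aux_from_primary <- function(location, scale, skewness) {
  scale <- as.matrix(scale)
  check_pd_scale(scale)
  location <- as.numeric(location)
  delta <- delta_from_alpha(skewness, scale)
  s <- sqrt(diag(scale))
  eta <- s * delta
  lam <- sym_part(scale - tcrossprod(eta))
  dd <- sqrt(pmax(1 - delta^2, 0))
  omega <- delta / dd
  corr <- scale_to_corr(scale)
  omega_bar <- sweep(sweep(corr, 1, dd, "/"), 2, dd, "/") - tcrossprod(omega)
  structure(
    list(location = location, sigma = diag(s, length(s)), corr = corr,
         delta = delta, eta = eta, lam = lam,
         d_delta = diag(dd, length(dd)), omega = omega,
         omega_bar = sym_part(omega_bar)),
    class = "component_aux")
}

#' Reconstruct (scale, skewness) from the conditional parameterization
#'
#' Inverse of \code{\link{aux_from_primary}}: \eqn{\Sigma = \Lambda +
#' \eta\eta^T}, \eqn{\delta_j = \eta_j / \sqrt{\Sigma_{jj}}}, then
#' \eqn{\alpha} via \code{\link{alpha_from_delta}}.  When \eqn{\Lambda} is
#' positive definite the implied \eqn{\delta} is automatically admissible
#' (\eqn{\eta^T\Sigma^{-1}\eta < 1} by Sherman--Morrison); \eqn{\delta} is
#' still clipped into \eqn{(-1+10^{-6},\,1-10^{-6})} to guard the boundary.
#'
#' @param location numeric p-vector (passed through unchanged).
#' @param lam symmetric p x p matrix \eqn{\Lambda} with smallest eigenvalue
#'   >= -1e-10; PSD repair of noisier matrices is
#'   \code{\link{psd_project}}'s job.
#' @param eta numeric p-vector.
#' @param delta_margin clip margin keeping \eqn{|\delta_j| \le 1 -}
#'   \code{delta_margin}.
#' @return list with \code{location}, \code{scale}, \code{skewness},
#'   \code{delta}, \code{eta}.
#' @export
primary_from_aux <- function(location, lam, eta, delta_margin = 1e-6) {
  lam <- as.matrix(lam)
  check_square_symmetric(lam, name = "lam")
  if (min_eigval(lam) < -1e-10)
    stop("lam has eigenvalues below -1e-10; apply psd_project first")
  eta <- as.numeric(eta)
  # The skewness inversion needs both |delta_j| < 1 and the quadratic form
  # delta' corr^{-1} delta < 1; after noise either can be violated, and the
  # inverted alpha diverges near the boundary.  Clip elementwise, then
  # shrink delta radially until the quadratic form respects the margin
  # (recomputing Sigma = Lambda + eta eta' each pass, since eta moves with
  # delta); for interior inputs the loop exits on the first pass untouched.
  for (pass in 1:20) {
    scale <- sym_part(lam + tcrossprod(eta))
    s <- sqrt(pmax(diag(scale), 0))
    if (any(s == 0)) stop("reconstructed scale has a zero diagonal entry")
    delta <- pmin(pmax(eta / s, -1 + delta_margin), 1 - delta_margin)
    eta <- s * delta
    q <- sum(delta * solve(scale_to_corr(scale), delta))
    if (q <= 1 - delta_margin) break
    delta <- delta * sqrt((1 - delta_margin) / q)
    eta <- s * delta
  }
  scale_pd <- scale
  if (min_eigval(scale_pd) <= 1e-12)
    scale_pd <- scale_pd + diag(1e-10, nrow(scale_pd))
  alpha <- alpha_from_delta(delta, scale_pd)
  list(location = as.numeric(location), scale = scale, skewness = alpha,
       delta = delta, eta = eta)
}

# Aux list for every component of a mixture_params object.
params_to_aux <- function(params) {
  lapply(seq_len(params$G), function(k)
    aux_from_primary(params$locations[[k]], params$scales[[k]],
                     params$skewness[[k]]))
}
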