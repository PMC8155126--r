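#' Repair noisy mixture weights onto the probability simplex
#'
#' Laplace noise leaves the released weights neither nonnegative nor
#' summing to one.  Two repair modes are offered, both finishing with the
#' same zeta smoothing \eqn{\hat\pi_k = (v_k + \zeta)/(\sum_j v_j + G\zeta)}:
#' \describe{
#'   \item{\code{"clip"} (default)}{negatives are set to zero first.  If all
#'     clipped weights are zero the smoothing alone yields the uniform
#'     vector.}
#'   \item{\code{"minmax"}}{rescales by \eqn{(v - \min v)/(\max v - \min v)}
#'     first.  This maps the smallest weight to 0 and the largest to 1
#'     regardless of the input, so for G = 2 the output is always about
#'     \eqn{(\zeta', 1-\zeta')} — a structural degeneracy; the mode is kept
#'     for fidelity comparisons, with \code{"clip"} as the recommended
#'     default.  Equal inputs (max = min) fall back to uniform 1/G.}
#' }
#'
#' @param noisy numeric length-G vector of perturbed weights.
#' @param zeta small positive smoothing constant (default 1e-3); zero is
#'   allowed in \code{"clip"} mode when at least one weight is positive.
#' @param mode \code{"clip"} or \code{"minmax"}.
#' @return simplex vector: nonnegative, sums to one within 1e-12.
#' @export
#' @examples
#' normalize_weights(c(-0.1, 0.6, 0.5), zeta = 1e-3, mode = "clip")
#' normalize_weights(c(0.2, 0.3, 0.5), zeta = 1e-3, mode = "minmax")
normalize_weights <- function(noisy, zeta = 1e-3, mode = c("clip", "minmax")) {
  mode <- match.arg(mode)
  v <- as.numeric(noisy)
  G <- length(v)
  if (G < 1) stop("empty weight vector")
  if (zeta < 0) stop("zeta must be >= 0")
  if (mode == "minmax") {
    if (G < 2 || max(v) == min(v)) {
      v <- rep(1 / G, G)
    } else {
      v <- (v - min(v)) / (max(v) - min(v))
    }
  } else {
    v <- pmax(v, 0)
  }
  den <- sum(v) + G * zeta
  if (den <= 0) return(rep(1 / G, G))
  out <- (v + zeta) / den
  out / sum(out)
}

#' Diagonal-shift projection onto the PSD cone
#'
#' Returns \eqn{M + \varrho(M) I} with \eqn{\varrho(M) = \max(0,
#' -\lambda_{\min}(M))}, the smallest nonnegative ridge making all
#' eigenvalues nonnegative.  A PSD input is returned unchanged
#' (idempotent).  Inputs are symmetrized first, since elementwise Laplace
#' noise drawn without the symmetric flag breaks symmetry.
#'
#' @param noisy square numeric matrix.
#' @return symmetric PSD matrix of the same size, with attribute
#'   \code{"ridge"} holding \eqn{\varrho}.
#' @export
#' @examples
#' psd_project(matrix(c(1, 2, 2, 1), 2))  # eigenvalues 3, -1 -> ridge 1
psd_project <- function(noisy) {
  m <- as.matrix(noisy)
  if (nrow(m) != ncol(m)) stop("input must be square")
  m <- sym_part(m)
  ridge <- max(0, -min_eigval(m))
  out <- m + diag(ridge, nrow(m))
  attr(out, "ridge") <- ridge
  out
}

#' Repair one component's noisy parameters
#'
#' Given the perturbed location \eqn{\bar\xi}, conditional scale
#' \eqn{\bar\Lambda} and skewness scale \eqn{\bar\eta} released by the noise
#' step, produces parameters valid for the next E-step:
#' \enumerate{
#'   \item \eqn{\hat\Lambda}: symmetrize, PSD-project
#'     (\code{\link{psd_project}}), then floor eigenvalues at
#'     \code{lam_floor} so the next E-step sees a strictly positive-definite
#'     conditional scale;
#'   \item \eqn{\hat\eta}: radial L1 clip to \code{eta_radius} when given,
#'     re-establishing the sensitivity hypothesis for the next iteration;
#'   \item \eqn{\hat\Sigma = \hat\Lambda + \hat\eta\hat\eta^T} (PSD by
#'     construction), \eqn{\hat\delta = \hat\sigma^{-1}\hat\eta} clipped
#'     into \eqn{(-1+10^{-6}, 1-10^{-6})}, and \eqn{\hat\alpha} by
#'     inversion.  A zero diagonal entry of \eqn{\hat\Sigma} gets a 1e-8
#'     jitter with a warning.
#' }
#' The location passes through unchanged; zero noise on already-valid
#' inputs reproduces their reconstruction exactly.
#'
#' The default \code{delta_margin} here (0.005) is deliberately much wider
#' than the boundary guard used elsewhere: when Laplace noise drives a
#' diagonal entry of \eqn{\bar\Lambda} to (near) zero, the implied
#' \eqn{|\delta_j|} reaches 1 and the inverted skewness
#' \eqn{|\alpha| \sim (1-\delta_j^2)^{-1/2}} diverges, turning the
#' component density into a numerical step function that destabilizes every
#' later E-step.  Capping \eqn{|\delta_j|} at 0.995 bounds the implied
#' one-dimensional skewness near 10, already indistinguishable from the
#' half-normal boundary in practice.
#'
#' @param noisy_xi numeric p-vector.
#' @param noisy_lam square p x p matrix (possibly asymmetric, indefinite).
#' @param noisy_eta numeric p-vector.
#' @param eta_radius optional L1 clip radius for \eqn{\hat\eta}.
#' @param lam_floor eigenvalue floor for \eqn{\hat\Lambda} (default 1e-8).
#' @param delta_margin post-noise clip margin for \eqn{\hat\delta}.
#' @return list with \code{location}, \code{scale}, \code{skewness},
#'   \code{lam}, \code{eta}, \code{delta}, \code{ridge}.
#' @export
repair_component <- function(noisy_xi, noisy_lam, noisy_eta,
                             eta_radius = NULL, lam_floor = 1e-8,
                             delta_margin = 0.005) {
  lam <- psd_project(noisy_lam)
  ridge <- attr(lam, "ridge")
  attr(lam, "ridge") <- NULL
  lam <- floor_eigenvalues(lam, lam_floor)
  eta <- as.numeric(noisy_eta)
  if (!is.null(eta_radius)) eta <- clip_vector_l1(eta, eta_radius)
  scale <- sym_part(lam + tcrossprod(eta))
  if (any(diag(scale) <= 0)) {
    warning("repaired scale has a non-positive diagonal entry; jittering")
    diag(scale) <- pmax(diag(scale), 1e-8)
  }
  rec <- primary_from_aux(as.numeric(noisy_xi), lam, eta,
                          delta_margin = delta_margin)
  c(rec[c("location", "scale", "skewness", "delta", "eta")],
    list(lam = lam, ridge = ridge))
}
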