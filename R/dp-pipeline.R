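#' (Differentially private) k-means initialization
#'
#' Lloyd's algorithm seeded at \code{G} random records.  With
#' \code{eps_init > 0} each iteration releases noisy cluster counts
#' (sensitivity 1) and noisy coordinate sums (sensitivity \code{R}, the L1
#' record radius), each receiving half of the per-iteration budget
#' \code{eps_init/iters} — the standard private-Lloyd construction.  With
#' \code{eps_init = 0} the updates are exact (non-private initialization, a
#' documented privacy caveat of the default pipeline configuration).
#'
#' The returned mixture uses uniform weights and moment-matched component
#' parameters built from each cluster's third-moment (Mardia-type) skewness
#' direction.  Marginal skewness coordinates are nearly useless here — a
#' component whose skewness is shared across coordinates shows almost no
#' skewness in any single margin — so the init standardizes the cluster
#' (\eqn{z = L^{-1}(x-\bar x)}), takes the direction \eqn{u \propto
#' E[z\|z\|^2]} of the third-moment tensor, computes the directional sample
#' skewness \eqn{\gamma_d = E[(u^{\top}z)^3]}, and inverts the skew-normal
#' skewness formula \eqn{\gamma_1 = \frac{4-\pi}{2} m^3 (1-m^2)^{-3/2}},
#' \eqn{m = \delta\sqrt{2/\pi}}, for the directional \eqn{\delta}.  The
#' implied \eqn{\eta}, location offset \eqn{\eta\sqrt{2/\pi}} and scale
#' correction \eqn{(2/\pi)\eta\eta^{\top}} are mapped back to the original
#' coordinates.  Starting near the right skew direction and magnitude
#' matters: the likelihood has rival modes with a component's skew
#' direction wrong and its location shifted in compensation, and EM does
#' not cross between them.
#'
#' @param data numeric n x p matrix.
#' @param G number of clusters/components.
#' @param eps_init privacy budget for initialization (0 = exact Lloyd).
#' @param iters Lloyd iterations (default 10).
#' @param seed integer seed; the same seed gives the identical
#'   initialization.
#' @param R L1 record radius used for the sum-query sensitivity when
#'   \code{eps_init > 0}.
#' @param gaussian if \code{TRUE}, skewness is initialized at zero.
#' @return a \code{\link{mixture_params}} object.
#' @export
dp_kmeans_init <- function(data, G, eps_init = 0, iters = 10, seed = 1L,
                           R = NULL, gaussian = FALSE) {
  X <- as_data_matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (G < 1) stop("G must be >= 1")
  if (n <= G) stop("need more records than clusters")
  if (eps_init > 0 && is.null(R))
    stop("private initialization needs the record radius R")
  local_seed(seed, {
    centers <- X[sample.int(n, G), , drop = FALSE]
    eps_it <- if (eps_init > 0) eps_init / iters else 0
    for (it in seq_len(iters)) {
      d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
        2 * X %*% t(centers)
      assign_k <- max.col(-d2, ties.method = "first")
      for (k in seq_len(G)) {
        idx <- assign_k == k
        cnt <- sum(idx)
        sums <- colSums(X[idx, , drop = FALSE])
        if (eps_it > 0) {
          cnt <- cnt + rlaplace(1, 2 / eps_it)          # S(count) = 1
          sums <- sums + rlaplace(p, 2 * R / eps_it)    # S(sum) = R
        }
        if (cnt >= 1) {
          centers[k, ] <- sums / cnt
        } else {
          centers[k, ] <- X[sample.int(n, 1L), ]        # re-seed empty cluster
        }
      }
    }
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign_k <- max.col(-d2, ties.method = "first")
    pooled <- stats::cov(X)
    scales <- vector("list", G); skew <- vector("list", G)
    locations <- vector("list", G)
    for (k in seq_len(G)) {
      idx <- which(assign_k == k)
      locations[[k]] <- centers[k, ]
      C <- if (length(idx) > p) stats::cov(X[idx, , drop = FALSE]) else pooled
      C <- floor_eigenvalues(sym_part(C), 1e-6)
      if (gaussian || length(idx) < 8) {
        scales[[k]] <- C
        skew[[k]] <- numeric(p)
      } else {
        xs <- X[idx, , drop = FALSE]
        mu <- colMeans(xs)
        L <- t(chol(C))
        z <- t(forwardsolve(L, t(xs) - mu))
        b <- colMeans(z * rowSums(z^2))
        if (sqrt(sum(b^2)) < 1e-8) {
          scales[[k]] <- C
          skew[[k]] <- numeric(p)
        } else {
          u <- b / sqrt(sum(b^2))
          gd <- mean(drop(z %*% u)^3)
          g_max <- 0.5 * (4 - pi) * (2 / pi)^1.5 / (1 - 2 / pi)^1.5
          gd <- min(max(gd, -0.95 * g_max), 0.95 * g_max)
          s3 <- 2 * gd / (4 - pi)
          m <- sign(s3) * abs(s3)^(1 / 3) / sqrt(1 + abs(s3)^(2 / 3))
          d_dir <- min(max(m / sqrt(2 / pi), -0.95), 0.95)
          # directional eta in standardized space, then back-transform
          c_dir <- d_dir / sqrt(1 - (2 / pi) * d_dir^2)
          eta <- drop(L %*% (c_dir * u))
          scale_k <- sym_part(C + (2 / pi) * tcrossprod(eta))
          delta <- eta / sqrt(diag(scale_k))
          q <- sum(delta * solve(scale_to_corr(scale_k), delta))
          if (q >= 0.95) {
            eta <- eta * sqrt(0.9 / q)
            scale_k <- sym_part(C + (2 / pi) * tcrossprod(eta))
            delta <- eta / sqrt(diag(scale_k))
          }
          locations[[k]] <- mu - eta * sqrt(2 / pi)
          scales[[k]] <- scale_k
          skew[[k]] <- alpha_from_delta(delta, scale_k)
        }
      }
    }
    mixture_params(rep(1 / G, G), locations, scales, skew)
  })
}

# Default pipeline configuration.
#' Pipeline configuration
#'
#' Collects the tuning knobs of the private pipeline: the weight-repair
#' mode and its smoothing constant, the eta-update denominator, the
#' eigenvalue floor applied to every conditional scale, the starvation
#' threshold below which a component is re-seeded, the initialization
#' budget/iterations, and the \code{no_noise} sentinel that turns the
#' pipeline into plain EM run for exactly T iterations (no clipping, no
#' noise, no repair) — useful for debugging and for validating the
#' zero-noise degeneracy.
#'
#' @param weights_mode \code{"clip"} or \code{"minmax"}
#'   (\code{\link{normalize_weights}}).
#' @param zeta weight smoothing constant.
#' @param eta_denominator \code{"second-moment"} or \code{"weights-only"}
#'   (\code{\link{m_step_eta}}).
#' @param lam_floor eigenvalue floor for conditional scales in the
#'   (non-private) M-step.
#' @param scale_floor_frac the repaired private conditional scales are
#'   floored at eigenvalue \code{(scale_floor_frac * R)^2}.  The
#'   diagonal-shift PSD projection returns a matrix whose smallest
#'   eigenvalue is exactly zero whenever its input is indefinite — which at
#'   small budgets is nearly every iteration — and a quasi-singular
#'   component makes the log-likelihood arbitrarily bad.  The default 0.05
#'   bounds component standard deviations below at 5 percent of the public
#'   record radius, a resolution below which a private density estimate
#'   carries no signal anyway.
#' @param starve_frac components with \eqn{N_k <} \code{starve_frac}\eqn{\cdot n}
#'   are re-seeded from a perturbed copy of the heaviest component.
#' @param eps_init,init_iters initialization budget and Lloyd iterations.
#' @param no_noise disable clipping, noise and repair.
#' @return a named list of class \code{"dp_config"}.
#' @export
dp_config <- function(weights_mode = c("clip", "minmax"), zeta = 1e-3,
                      eta_denominator = c("second-moment", "weights-only"),
                      lam_floor = 1e-8, scale_floor_frac = 0.05,
                      starve_frac = 1e-6,
                      eps_init = 0, init_iters = 10, no_noise = FALSE) {
  structure(list(weights_mode = match.arg(weights_mode), zeta = zeta,
                 eta_denominator = match.arg(eta_denominator),
                 lam_floor = lam_floor, scale_floor_frac = scale_floor_frac,
                 starve_frac = starve_frac,
                 eps_init = eps_init, init_iters = init_iters,
                 no_noise = isTRUE(no_noise)),
            class = "dp_config")
}

# Re-seed starved components from a perturbed copy of the heaviest one.
reseed_starved <- function(state, nk, n, starve_frac, p) {
  starved <- which(nk < starve_frac * n)
  if (length(starved) == 0) return(state)
  donor <- which.max(nk)
  for (k in starved) {
    jit <- rlaplace(p, 0.1 * sqrt(mean(diag(state$lam_list[[donor]]))))
    state$locations[[k]] <- state$locations[[donor]] + jit
    state$lam_list[[k]] <- state$lam_list[[donor]]
    state$eta_list[[k]] <- state$eta_list[[donor]]
    state$weights[k] <- state$weights[donor] / 2
    state$weights[donor] <- state$weights[donor] / 2
    state$weights <- state$weights / sum(state$weights)
  }
  state
}

dp_fit_internal <- function(data, G, eps_total, T_iter, bounds, config,
                            seed, family) {
  X <- as_data_matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (n <= 2 * G) stop("need n > 2G records")
  if (T_iter < 1) stop("T must be >= 1")
  if (!config$no_noise) {
    if (!inherits(bounds, "sensitivity_bounds"))
      stop("bounds must be a sensitivity_bounds object")
    if (eps_total <= 0) stop("eps_total must be > 0")
    if (max(apply(X, 2, stats::var)) <= 0)
      stop("degenerate data: all records identical")
    X <- clip_records(X, bounds$R)
  }
  private <- !config$no_noise
  # per-target fractions are fixed; the Gaussian baseline has no eta target,
  # so its share flows into the per-iteration residual (the weights), keeping
  # the composition total at eps_total
  fractions <- if (family == "gmm")
    c(lambda = 0.6, xi = 0.13, eta = 0) else c(lambda = 0.6, xi = 0.13,
                                               eta = 0.13)
  budget <- if (private)
    allocate_budget(eps_total, T_iter, G, fractions, config$eps_init)
  else NULL
  sens <- if (private)
    list(pi = sensitivity_pi(G, n), xi = sensitivity_xi(G, n, bounds),
         eta = sensitivity_eta(G, n, bounds),
         lambda = sensitivity_lambda(G, n, bounds))
  else NULL

  init <- dp_kmeans_init(X, G, eps_init = if (private) config$eps_init else 0,
                         iters = config$init_iters, seed = seed,
                         R = if (private) bounds$R else NULL,
                         gaussian = (family == "gmm"))
  state <- state_from_params(init)
  if (private)
    state$eta_list <- lapply(state$eta_list, clip_vector_l1,
                             radius = bounds$R3)
  clip <- if (private)
    list(r1_max = bounds$R1, r2_min = bounds$R2, r2_max = bounds$R2_hi,
         eta_radius = bounds$R3)
  else NULL

  audit <- vector("list", T_iter)
  trace <- numeric(T_iter)
  trajectory <- vector("list", T_iter)
  local_seed(if (private) derive_seed(seed, 1L) else NULL, {
    for (t in seq_len(T_iter)) {
      # starvation guard: noise can annihilate a component mid-run, leaving
      # an (almost) empty responsibility column that breaks the M-step
      stats <- estep_state(X, state)
      if (private) {
        attempt <- 0L
        while (any(stats$nk < config$starve_frac * n) && attempt < 3L) {
          state <- reseed_starved(state, stats$nk, n, config$starve_frac, p)
          stats <- estep_state(X, state)
          attempt <- attempt + 1L
        }
      }
      step <- em_iteration(X, state, clip = clip,
                           eta_denominator = config$eta_denominator,
                           family = family, lam_floor = config$lam_floor,
                           stats = stats)
      state <- step$state
      if (private) {
        rows <- list()
        b_pi <- sens$pi / budget$eps_pi
        state$weights <- laplace_perturb(state$weights, b_pi)
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = t, target = "pi", component = NA_integer_,
          sensitivity = sens$pi, epsilon = budget$eps_pi, scale = b_pi)
        b_xi <- sens$xi / budget$eps_xi
        b_lam <- sens$lambda / budget$eps_lambda
        b_eta <- if (family == "gmm") 0 else sens$eta / budget$eps_eta
        for (k in seq_len(G)) {
          state$locations[[k]] <- laplace_perturb(state$locations[[k]], b_xi)
          rows[[length(rows) + 1L]] <- data.frame(
            iteration = t, target = "xi", component = k,
            sensitivity = sens$xi, epsilon = budget$eps_xi, scale = b_xi)
          state$lam_list[[k]] <- laplace_perturb(state$lam_list[[k]], b_lam,
                                                 symmetric = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            iteration = t, target = "lambda", component = k,
            sensitivity = sens$lambda, epsilon = budget$eps_lambda,
            scale = b_lam)
          if (family != "gmm") {
            state$eta_list[[k]] <- laplace_perturb(state$eta_list[[k]], b_eta)
            rows[[length(rows) + 1L]] <- data.frame(
              iteration = t, target = "eta", component = k,
              sensitivity = sens$eta, epsilon = budget$eps_eta,
              scale = b_eta)
          }
        }
        audit[[t]] <- do.call(rbind, rows)
        # post-processing: repair weights, PSD-project scales, re-clip eta
        state$weights <- normalize_weights(state$weights, config$zeta,
                                           config$weights_mode)
        for (k in seq_len(G)) {
          rep_k <- repair_component(state$locations[[k]],
                                    state$lam_list[[k]],
                                    state$eta_list[[k]],
                                    eta_radius = if (family == "gmm") NULL
                                                 else bounds$R3,
                                    lam_floor = max(config$lam_floor,
                                      (config$scale_floor_frac * bounds$R)^2))
          state$locations[[k]] <- rep_k$location
          state$lam_list[[k]] <- rep_k$lam
          state$eta_list[[k]] <- if (family == "gmm")
            numeric(p) else rep_k$eta
        }
      }
      trajectory[[t]] <- params_from_state(state, p)
      trace[t] <- loglik_mean(X, trajectory[[t]])
    }
  })
  noise_audit <- if (private) do.call(rbind, audit) else empty_noise_audit()
  new_fit_result(trajectory[[T_iter]], trajectory, trace, n, family, seed,
                 noise_audit, converged = NA,
                 eps_total = if (private) eps_total else Inf,
                 T_iter = as.integer(T_iter))
}

#' Differentially private skew-normal mixture fit
#'
#' Runs exactly \code{T_iter} EM iterations on the record-clipped data.
#' Each iteration performs the E-step, clips the conditional moments and
#' the skewness-scale update so the closed-form sensitivity bounds apply,
#' perturbs the released blocks \eqn{(\pi, \xi_k, \eta_k, \Lambda_k)} with
#' Laplace noise at scales \eqn{S(\cdot)/\varepsilon_{(\cdot)}}
#' (\code{\link{sensitivities}}, \code{\link{allocate_budget}}), and repairs
#' the noisy parameters (\code{\link{normalize_weights}},
#' \code{\link{repair_component}}).  The derived \eqn{(\hat\Sigma_k,
#' \hat\alpha_k)} re-enter the next iteration, so every quantity crossing
#' an iteration boundary is a post-processed function of noisy statistics
#' only, and sequential composition gives \eqn{\varepsilon}-differential
#' privacy overall.  Every noise application is logged in
#' \code{noise_audit} (iteration, target, component, sensitivity, epsilon,
#' scale).
#'
#' Early stopping is disabled: the budget is pre-committed across
#' \code{T_iter} iterations.  With \code{config$no_noise = TRUE} the run is
#' identical (bitwise, at equal seed) to \code{\link{fit_em}} for
#' \code{T_iter} iterations.
#'
#' @param data numeric n x p matrix (n > 2G).
#' @param G number of components.
#' @param eps_total total privacy budget.
#' @param T_iter iteration count the budget is split across (default 30).
#' @param bounds \code{\link{sensitivity_bounds}}.
#' @param config \code{\link{dp_config}}.
#' @param seed integer seed driving initialization and all noise.
#' @return a \code{"dpskewmix_fit"} object (see \code{\link{fit_em}}) with a
#'   populated \code{noise_audit} log.
#' @export
fit_dp_msnm <- function(data, G, eps_total, T_iter = 30, bounds,
                        config = dp_config(), seed = 1L) {
  dp_fit_internal(data, G, eps_total, T_iter, bounds, config, seed, "msnm")
}

#' Differentially private Gaussian mixture baseline
#'
#' Same pipeline as \code{\link{fit_dp_msnm}} with skewness frozen at zero:
#' the \eqn{\eta} update and its noise are skipped and the location block
#' absorbs the freed budget fraction (0.26 instead of 0.13), so the
#' composition still closes at \code{eps_total}.  With zero noise this is a
#' standard Gaussian-mixture EM.
#'
#' @inheritParams fit_dp_msnm
#' @return a \code{"dpskewmix_fit"} object.
#' @export
fit_dp_gmm <- function(data, G, eps_total, T_iter = 30, bounds,
                       config = dp_config(), seed = 1L) {
  dp_fit_internal(data, G, eps_total, T_iter, bounds, config, seed, "gmm")
}
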