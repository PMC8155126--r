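test_that("truncated-normal moments match the integration oracle and stay stable", {
  m <- truncnorm_moments(0, 1)
  expect_equal(m$m1, sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(m$m2, 1, tolerance = 1e-12)
  for (mu in c(1, -1, 2.5, -10)) {
    got <- truncnorm_moments(mu, 1)
    want <- oracle_truncnorm_moments(mu, 1)
    expect_equal(got$m1, want$m1, tolerance = 1e-7)
    expect_equal(got$m2, want$m2, tolerance = 1e-7)
  }
  # known value at mu = 1: Delta = phi(1)/Phi(1)
  d1 <- stats::dnorm(1) / stats::pnorm(1)
  expect_equal(truncnorm_moments(1, 1)$m1, 1 + d1, tolerance = 1e-12)
  expect_equal(truncnorm_moments(1, 1)$m2, 2 + d1, tolerance = 1e-12)
  # deep-tail stability: positive, finite, ordered
  z <- c(-50, -1e3, -1e4)
  deep <- truncnorm_moments(z, 1)
  expect_true(all(is.finite(deep$m1)) && all(deep$m1 > 0))
  expect_true(all(is.finite(deep$m2)) && all(deep$m2 > 0))
  # moment inequalities over a grid
  grid <- truncnorm_moments(seq(-30, 30, by = 0.5), 2)
  expect_true(all(grid$m2 >= grid$m1^2))
  # m1 exceeds max(0, mu); far in the right tail the excess underflows,
  # so equality is allowed there
  expect_true(all(grid$m1 >= pmax(0, seq(-30, 30, by = 0.5))))
  expect_true(all(grid$m1[seq(-30, 30, by = 0.5) <= 10] >
                    pmax(0, seq(-30, 30, by = 0.5))[seq(-30, 30, by = 0.5) <= 10]))
  expect_error(truncnorm_moments(0, 0), "sd")
})

test_that("E-step responsibilities follow Bayes' rule and the moment formulas", {
  mp <- test_mixture()
  X <- generate_mixture(scenario(n = 200, params = mp, seed = 3))$data
  st <- e_step(X, mp)
  expect_equal(rowSums(st$r0), rep(1, 200), tolerance = 1e-10)
  expect_true(all(st$r0 >= 0 & st$r0 <= 1))
  expect_true(all(st$r1 >= 0))
  expect_true(all(st$r2 >= st$r1^2 - 1e-12))
  expect_equal(sum(st$nk), 200, tolerance = 1e-8)
  # G = 1: all responsibilities are one
  one <- mixture_params(1, mp$locations[1], mp$scales[1], mp$skewness[1])
  expect_true(all(e_step(X, one)$r0 == 1))
  # two symmetric normal components: Bayes-rule oracle at a far point
  two <- mixture_params(c(0.5, 0.5), list(-10, 10),
                        list(matrix(1), matrix(1)), list(0, 0))
  r <- e_step(matrix(-10), two)$r0
  num <- stats::dnorm(-10, c(-10, 10))
  expect_equal(as.numeric(r), num / sum(num), tolerance = 1e-6)
  expect_lt(abs(r[1] - 1), 1e-6)
  # sign of the truncation mean: eta > 0 and x > xi gives mu_tau > 0
  sk <- mixture_params(1, list(0), list(matrix(1)), list(2))
  stp <- e_step(matrix(1.5), sk)
  expect_gt(stp$mu_tau[1, 1], 0)
})

test_that("closed-form M-step updates match hand arithmetic", {
  # pi: column means of r0
  st <- list(r0 = rbind(c(1, 0), c(0, 1)))
  expect_equal(m_step_pi(st, 2), c(0.5, 0.5))
  st2 <- list(r0 = rbind(c(0.9, 0.1), c(0.9, 0.1)))
  expect_equal(m_step_pi(st2, 2), c(0.9, 0.1))
  set.seed(5)
  r <- matrix(stats::runif(100), 50, 2); r <- r / rowSums(r)
  expect_equal(m_step_pi(list(r0 = r), 50), colMeans(r))
  expect_equal(sum(m_step_pi(list(r0 = r), 50)), 1)
  # xi: hand case n=2, G=1, r1=(1,1), eta=1, x=(0,2) -> 0
  stats1 <- list(r0 = matrix(1, 2, 1), r1 = matrix(1, 2, 1),
                 r2 = matrix(1, 2, 1))
  expect_equal(m_step_xi(matrix(c(0, 2)), stats1, list(1))[[1]], 0)
  # eta: hand case xi=1 -> 0
  expect_equal(m_step_eta(matrix(c(0, 2)), stats1, list(1))[[1]], 0)
  # lambda: hand case xi=1, eta=0.5 -> 1.25
  expect_equal(m_step_lambda(matrix(c(0, 2)), stats1, list(1),
                             list(0.5))[[1]], matrix(1.25))
  # eta = 0 reduces xi to the weighted mean and lambda to a weighted cov
  mp <- test_mixture()
  X <- generate_mixture(scenario(n = 60, params = mp, seed = 8))$data
  st3 <- e_step(X, mp)
  xi0 <- m_step_xi(X, st3, list(c(0, 0), c(0, 0)))
  for (k in 1:2)
    expect_equal(xi0[[k]], colSums(st3$r0[, k] * X) / sum(st3$r0[, k]),
                 tolerance = 1e-12)
  lam0 <- m_step_lambda(X, st3, xi0, list(c(0, 0), c(0, 0)))
  for (k in 1:2) {
    ctr <- sweep(X, 2, xi0[[k]])
    expect_equal(lam0[[k]], crossprod(ctr * st3$r0[, k], ctr) /
                   sum(st3$r0[, k]), tolerance = 1e-10)
    expect_identical(lam0[[k]], t(lam0[[k]]))
  }
  # record-permutation invariance
  perm <- sample(nrow(X))
  stp <- list(r0 = st3$r0[perm, , drop = FALSE],
              r1 = st3$r1[perm, , drop = FALSE],
              r2 = st3$r2[perm, , drop = FALSE])
  aux <- lapply(1:2, function(k) c(0.1, -0.2))
  expect_equal(m_step_xi(X[perm, ], stp, aux), m_step_xi(X, st3, aux),
               tolerance = 1e-12)
})

test_that("each M-step update maximizes the Q-function numerically", {
  set.seed(31)
  X <- matrix(stats::rnorm(6), ncol = 1)
  mp <- mixture_params(1, list(0.2), list(matrix(1.3)), list(0.8))
  st <- e_step(X, mp)
  ax <- aux_from_primary(mp$locations[[1]], mp$scales[[1]], mp$skewness[[1]])
  qf <- function(xi, eta, lam)
    dpskewmix:::q_function(X, st, 1, list(xi), list(eta), list(matrix(lam)))
  # xi update given the current eta
  xi_new <- m_step_xi(X, st, list(ax$eta))[[1]]
  opt_xi <- stats::optimize(function(v) qf(v, ax$eta, ax$lam[1, 1]),
                            c(-5, 5), maximum = TRUE)$maximum
  expect_equal(xi_new, opt_xi, tolerance = 1e-5)
  # eta update given the new xi
  eta_new <- m_step_eta(X, st, list(xi_new))[[1]]
  opt_eta <- stats::optimize(function(v) qf(xi_new, v, ax$lam[1, 1]),
                             c(-5, 5), maximum = TRUE)$maximum
  expect_equal(eta_new, opt_eta, tolerance = 1e-5)
  # lambda update given both
  lam_new <- m_step_lambda(X, st, list(xi_new), list(eta_new))[[1]][1, 1]
  opt_lam <- stats::optimize(function(v) qf(xi_new, eta_new, v),
                             c(1e-3, 20), maximum = TRUE)$maximum
  expect_equal(lam_new, opt_lam, tolerance = 1e-5)
})

test_that("information criteria and parameter counts are consistent", {
  expect_identical(count_free_params(2, 2, "msnm"), 15L)
  expect_identical(count_free_params(3, 2, "gmm"), 17L)
  expect_identical(count_free_params(1, 1, "msnm"), 3L)
  expect_error(count_free_params(2, 2, "other"))
  ib <- aic_bic(-100, 5, 100)
  expect_equal(ib$aic, 210)
  expect_equal(aic_bic(-100, 5, exp(2))$bic, 210, tolerance = 1e-10)
  # aic < bic exactly when log n > 2
  expect_lt(aic_bic(-10, 3, 100)$aic, aic_bic(-10, 3, 100)$bic)
  expect_gt(aic_bic(-10, 3, 5)$aic, aic_bic(-10, 3, 5)$bic)
})

test_that("mean log-likelihood behaves as an average", {
  mp <- test_mixture()
  X <- generate_mixture(scenario(n = 100, params = mp, seed = 2))$data
  expect_equal(loglik_mean(rbind(X, X), mp), loglik_mean(X, mp),
               tolerance = 1e-12)
  expect_equal(loglik_mean(X[1, , drop = FALSE], mp),
               msnm_logpdf(X[1, ], mp), tolerance = 1e-12)
  # Gaussian entropy limit
  z <- matrix(stats::rnorm(1e4, 0, 1), ncol = 1)
  g1 <- mixture_params(1, list(0), list(matrix(1)), list(0))
  expect_equal(loglik_mean(z, g1), -0.5 * (1 + log(2 * pi)),
               tolerance = 0.05)
})

test_that("EM fits are deterministic, monotone, and near-stationary at the truth", {
  mp <- default_scenarios()$recovery$params
  X <- generate_mixture(scenario(n = 500, params = mp, seed = 17))$data
  f1 <- fit_em(X, 2, seed = 3, max_iter = 40)
  f2 <- fit_em(X, 2, seed = 3, max_iter = 40)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))
  expect_length(f1$loglik_trace, f1$n_iter)
  # starting at the truth, the first iteration barely moves the likelihood
  f3 <- fit_em(X, 2, init = mp, max_iter = 2, tol = 0)
  expect_lt(abs(f3$loglik_trace[2] - f3$loglik_trace[1]), 0.01)
})

test_that("with zero skewness the EM is an exact Gaussian-mixture EM", {
  # G = 1: closed-form Gaussian MLE
  set.seed(9)
  X <- matrix(stats::rnorm(400), ncol = 2)
  f <- fit_em(X, 1, family = "gmm", max_iter = 50)
  expect_equal(f$params$locations[[1]], colMeans(X), tolerance = 1e-6)
  ctr <- sweep(X, 2, colMeans(X))
  expect_equal(f$params$scales[[1]], crossprod(ctr) / nrow(X),
               tolerance = 1e-6)
  expect_equal(f$params$skewness[[1]], c(0, 0))
  # G = 2: trajectory matches an independently written GMM EM
  mp <- mixture_params(c(0.5, 0.5), list(c(-2, 0), c(2, 0)),
                       list(diag(2), diag(2)))
  X2 <- generate_mixture(scenario(n = 300, params = mp, seed = 5))$data
  init <- dp_kmeans_init(X2, 2, eps_init = 0, seed = 1, gaussian = TRUE)
  f2 <- fit_em(X2, 2, init = init, family = "gmm", max_iter = 8, tol = 0)
  traj <- oracle_gmm_em(X2, init$weights, init$locations, init$scales, 8)
  for (it in c(1, 4, 8)) {
    expect_equal(f2$trajectory[[it]]$weights, traj[[it]]$weights,
                 tolerance = 1e-6)
    for (k in 1:2) {
      expect_equal(f2$trajectory[[it]]$locations[[k]],
                   traj[[it]]$means[[k]], tolerance = 1e-6)
      expect_equal(f2$trajectory[[it]]$scales[[k]],
                   traj[[it]]$covs[[k]], tolerance = 1e-6)
    }
  }
})
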