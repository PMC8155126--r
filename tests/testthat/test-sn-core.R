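test_that("skew-normal log-density matches closed forms and reduces to the normal", {
  # alpha = 0, standard normal at the origin
  expect_equal(msn_logpdf(0, 0, matrix(1), 0), log(stats::dnorm(0)),
               tolerance = 1e-12)
  # scalar density 2 phi(1) Phi(1), computed with R's own normal oracle
  expect_equal(exp(msn_logpdf(1, 0, matrix(1), 1)),
               2 * stats::dnorm(1) * stats::pnorm(1), tolerance = 1e-12)
  # reflection symmetry of the density
  expect_equal(msn_logpdf(0.5, 0, matrix(1), 2),
               msn_logpdf(-0.5, 0, matrix(1), -2), tolerance = 1e-12)
  # alpha = 0 equals the multivariate normal log-density, randomized
  set.seed(42)
  for (i in 1:10) {
    p <- sample(1:3, 1)
    mp <- random_mixture(1, p)
    x <- stats::rnorm(p)
    expect_equal(msn_logpdf(x, mp$locations[[1]], mp$scales[[1]], numeric(p)),
                 as.numeric(oracle_dmvnorm_log(x, mp$locations[[1]],
                                               mp$scales[[1]])),
                 tolerance = 1e-10)
    # reflection with generic parameters
    a <- stats::runif(p, -2, 2)
    expect_equal(msn_logpdf(2 * mp$locations[[1]] - x, mp$locations[[1]],
                            mp$scales[[1]], -a),
                 msn_logpdf(x, mp$locations[[1]], mp$scales[[1]], a),
                 tolerance = 1e-12)
  }
})

test_that("density integrates to one in p = 1 and p = 2", {
  f1 <- function(x) exp(msn_logpdf(matrix(x, ncol = 1), 0.3, matrix(1.5), 2))
  expect_equal(stats::integrate(f1, -15, 15, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # p = 2 on a grid
  g <- seq(-8, 8, length.out = 321)
  h <- g[2] - g[1]
  X <- as.matrix(expand.grid(g, g))
  dens <- exp(msn_logpdf(X, c(0, 0.5), matrix(c(1, 0.4, 0.4, 1.5), 2),
                         c(2, -1)))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-4)
})

test_that("mixture log-density is a log-sum-exp of the components", {
  mp <- test_mixture()
  x <- c(0.3, -0.2)
  # G = 1 degenerates to the component density
  one <- mixture_params(1, mp$locations[1], mp$scales[1], mp$skewness[1])
  expect_equal(msnm_logpdf(x, one),
               msn_logpdf(x, mp$locations[[1]], mp$scales[[1]],
                          mp$skewness[[1]]), tolerance = 1e-12)
  # identical components collapse by convexity
  dup <- mixture_params(c(0.5, 0.5), mp$locations[c(1, 1)],
                        mp$scales[c(1, 1)], mp$skewness[c(1, 1)])
  expect_equal(msnm_logpdf(x, dup), msnm_logpdf(x, one), tolerance = 1e-12)
  # two normal components, direct two-term sum oracle
  two <- mixture_params(c(0.3, 0.7), list(-5, 5),
                        list(matrix(1), matrix(1)), list(0, 0))
  expect_equal(msnm_logpdf(5, two),
               log(0.3 * stats::dnorm(10) + 0.7 * stats::dnorm(0)),
               tolerance = 1e-12)
})

test_that("alpha/delta conversions invert each other", {
  expect_equal(delta_from_alpha(c(0, 0), diag(2)), c(0, 0))
  expect_equal(delta_from_alpha(1, matrix(1)), 1 / sqrt(2),
               tolerance = 1e-9)
  expect_equal(alpha_from_delta(1 / sqrt(2), matrix(1)), 1,
               tolerance = 1e-9)
  expect_equal(alpha_from_delta(delta_from_alpha(c(1, -2), diag(2)),
                                diag(2)), c(1, -2), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:20) {
    p <- 3
    S <- diag(0.5, p) + crossprod(matrix(stats::runif(p * p, -0.4, 0.4), p))
    a <- stats::runif(p, -3, 3)
    d <- delta_from_alpha(a, S)
    expect_true(all(abs(d) < 1))
    expect_equal(alpha_from_delta(d, S), a, tolerance = 1e-9)
    # round trip the other way
    expect_equal(delta_from_alpha(alpha_from_delta(d, S), S), d,
                 tolerance = 1e-9)
  }
})

test_that("auxiliary parameterization satisfies its identities", {
  # eta = 0 when alpha = 0
  a0 <- aux_from_primary(c(0, 0), diag(2), c(0, 0))
  expect_equal(a0$eta, c(0, 0))
  expect_equal(a0$lam, diag(2))
  # constructed case: Sigma = diag(2,1), delta chosen so eta = (1, 0)
  S <- diag(c(2, 1))
  alpha <- alpha_from_delta(c(1 / sqrt(2), 0), S)
  ax <- aux_from_primary(c(0, 0), S, alpha)
  expect_equal(ax$eta, c(1, 0), tolerance = 1e-10)
  expect_equal(ax$lam, diag(c(1, 1)), tolerance = 1e-10)
  set.seed(11)
  for (i in 1:20) {
    mp <- random_mixture(1, 3)
    ax <- aux_from_primary(mp$locations[[1]], mp$scales[[1]],
                           mp$skewness[[1]])
    # Lambda + eta eta' reconstructs Sigma
    expect_equal(ax$lam + tcrossprod(ax$eta), mp$scales[[1]],
                 tolerance = 1e-10)
    expect_true(all(abs(ax$delta) < 1))
    expect_true(min(eigen(ax$lam, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
    # full round trip through the conditional parameterization
    rec <- primary_from_aux(mp$locations[[1]], ax$lam, ax$eta)
    expect_equal(rec$scale, mp$scales[[1]], tolerance = 1e-8)
    expect_equal(rec$skewness, mp$skewness[[1]], tolerance = 1e-7)
  }
  # scalar arithmetic case: Lambda = 1, eta = 0.5
  rec <- primary_from_aux(0, matrix(1), 0.5)
  expect_equal(rec$scale, matrix(1.25))
  expect_equal(rec$delta, 0.5 / sqrt(1.25), tolerance = 1e-10)
  # eta = 0 gives Sigma = Lambda and alpha = 0
  rec0 <- primary_from_aux(c(1, 2), diag(2), c(0, 0))
  expect_equal(rec0$scale, diag(2))
  expect_equal(rec0$skewness, c(0, 0))
})

test_that("invalid parameters are rejected", {
  expect_error(msn_logpdf(0, 0, matrix(-1), 0), "positive definite")
  expect_error(msn_logpdf(0, c(0, 0), matrix(1), 0), "dimension")
  expect_error(alpha_from_delta(1.2, matrix(1)), "delta")
  expect_error(delta_from_alpha(1, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(primary_from_aux(0, matrix(c(1, 2, 2, 1), 2), c(0, 0)),
               "psd_project")
  expect_error(mixture_params(c(0.5, 0.6), list(0, 0),
                              list(matrix(1), matrix(1))), "sum to 1")
})

test_that("sampling follows the stochastic representation", {
  # determinism under a fixed seed, and the caller's RNG is untouched
  set.seed(123); before <- stats::runif(1)
  x1 <- sample_msn(50, c(0, 0), diag(2), c(1, -1), seed = 9)
  x2 <- sample_msn(50, c(0, 0), diag(2), c(1, -1), seed = 9)
  expect_identical(x1, x2)
  set.seed(123); expect_identical(stats::runif(1), before)
  # closed-form mean: xi + sigma delta sqrt(2/pi)
  n <- 1e5
  x <- sample_msn(n, 0, matrix(1), 1, seed = 4)
  delta <- 1 / sqrt(2)
  se <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - delta * sqrt(2 / pi)), 4 * se)
  # alpha = 0 reduces to the normal
  y <- sample_msn(n, c(1, -1), diag(c(1, 2)), c(0, 0), seed = 5)
  expect_lt(max(abs(colMeans(y) - c(1, -1))),
            4 * sqrt(2 / n) * 2)
  # randomized parameters against the closed-form mean
  set.seed(21)
  mp <- random_mixture(1, 2)
  ax <- aux_from_primary(mp$locations[[1]], mp$scales[[1]], mp$skewness[[1]])
  z <- sample_msn(n, mp$locations[[1]], mp$scales[[1]], mp$skewness[[1]],
                  seed = 6)
  want <- mp$locations[[1]] + ax$eta * sqrt(2 / pi)
  expect_lt(max(abs(colMeans(z) - want)),
            4 * max(apply(z, 2, stats::sd)) / sqrt(n))
})
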