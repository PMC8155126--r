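# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All user-facing randomness goes through
# this so that no function disturbs the global RNG stream.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) s <- (s * 48271 + as.double(k) * 104729 + 1) %% 2147483629
  as.integer(s) + 1L
}

as_data_matrix <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("data must be numeric")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("data contains non-finite values")
  x
}

check_square_symmetric <- function(m, tol = 1e-10, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be a square matrix", name))
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("%s must be symmetric (max asymmetry > %g)", name, tol))
  invisible(TRUE)
}

sym_part <- function(m) (m + t(m)) / 2

min_eigval <- function(m) {
  min(eigen(sym_part(m), symmetric = TRUE, only.values = TRUE)$values)
}

# log Phi(x), numerically stable over the whole real line.
log_phi_cdf <- function(x) stats::pnorm(x, log.p = TRUE)

# Multivariate normal log-density, rows of X, via Cholesky.
dmvnorm_log <- function(X, mean, sigma) {
  X <- rbind(X)
  p <- ncol(X)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("scale matrix is not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, t(X) - mean, transpose = TRUE)
  -0.5 * (p * log(2 * pi) + logdet + colSums(z^2))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
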