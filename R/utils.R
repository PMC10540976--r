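# Internal utilities shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so package internals never perturb user
# simulations.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Symmetrize a nearly-symmetric matrix (guards accumulated round-off).
symmetrize <- function(A) (A + t(A)) / 2

# log-determinant of a symmetric positive-definite matrix via Cholesky.
logdet_spd <- function(A) {
  2 * sum(log(diag(chol(symmetrize(A)))))
}

# Solve A X = B for symmetric positive-definite A.
solve_spd <- function(A, B) {
  R <- chol(symmetrize(A))
  backsolve(R, forwardsolve(t(R), B))
}

# Expand a noise covariance specification to a dense matrix of size n.
# `sigma_y` may be a scalar, a diagonal vector of length n_y, or an
# n_y x n_y matrix; when n is a multiple of n_y the block is tiled along
# the diagonal (independent noise across time points).
expand_sigma <- function(sigma_y, n) {
  if (is.matrix(sigma_y)) {
    n_y <- nrow(sigma_y)
    if (n == n_y) return(sigma_y)
    k <- n / n_y
    if (k != round(k)) stop("row count is not a multiple of dim(sigma_y)")
    out <- matrix(0, n, n)
    for (i in seq_len(k)) {
      idx <- ((i - 1L) * n_y + 1L):(i * n_y)
      out[idx, idx] <- sigma_y
    }
    out
  } else {
    diag(rep_len(as.numeric(sigma_y), n), n, n)
  }
}

# Per-row noise precision weights for a diagonal sigma_y (vector/scalar).
sigma_is_diagonal <- function(sigma_y) !is.matrix(sigma_y)

# Multivariate normal log-density with SPD covariance.
mvn_logdensity <- function(x, mean, cov) {
  r <- as.numeric(x - mean)
  R <- chol(symmetrize(cov))
  z <- forwardsolve(t(R), r)
  -0.5 * length(r) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}
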