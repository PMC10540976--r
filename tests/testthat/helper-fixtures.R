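# Shared fixtures: tiny dimensions, seeded conditions, a scalar-loop step
# oracle independent of the vectorised implementation, and a linear
# surrogate model with closed-form Bayesian posterior.

tiny_dims <- function(n_s = 2L, n_m = 1L, n_u = 1L, n_h = 3L,
                      n_tau = 3L) {
  mirnn_dims(n_s, n_m, n_u, n_h, n_tau)
}

seeded_condition <- function(dims, seed = 1L, n_tau = dims$n_tau,
                             s0 = NULL) {
  set.seed(seed)
  if (is.null(s0)) s0 <- runif(dims$n_s, 0.1, 1)
  mirnn_condition(
    s0 = s0,
    m0 = runif(dims$n_m, 0.1, 1),
    controls = matrix(runif((n_tau + 1) * dims$n_u), n_tau + 1,
                      dims$n_u),
    times = seq(0, n_tau))
}

# Scalar-loop reference of one step: explicit sums, no matrix algebra.
step_oracle <- function(params, s, m, u_prev, u_curr, mode = "inference",
                        constrained = TRUE, slope = 0.01) {
  dims <- attr(params, "dims")
  x <- c(s, m, u_prev, u_curr)
  h_prev <- params$h  # caller stores current latent in params$h
  a <- numeric(dims$n_h)
  for (k in seq_len(dims$n_h)) {
    acc <- params$b_hh[k]
    for (j in seq_len(dims$n_h)) acc <- acc + params$W_hh[k, j] * h_prev[j]
    for (i in seq_along(x)) acc <- acc + params$W_ih[i, k] * x[i]
    a[k] <- acc
  }
  h <- ifelse(a > 0, a, slope * a)
  o <- numeric(dims$n_y)
  for (y in seq_len(dims$n_y)) {
    acc <- params$b_ho[y]
    for (k in seq_len(dims$n_h)) acc <- acc + params$W_ho[k, y] * h[k]
    o[y] <- acc
  }
  s_out <- o[seq_len(dims$n_s)]
  m_out <- if (dims$n_m > 0) o[(dims$n_s + 1):dims$n_y] else numeric(0)
  if (constrained) s_out <- s_out * (s > 0)
  if (mode == "inference") {
    s_out <- pmax(s_out, 0); m_out <- pmax(m_out, 0)
  }
  list(s = s_out, m = m_out, h = h)
}

# Linear surrogate: conditions carry their own design matrix G, the model
# is y = G theta. MAP/Hessian/predictive have exact closed forms.
linear_model <- function(n_theta, n_y) {
  structure(list(
    n_theta = n_theta, n_y = n_y, dims = NULL, constrained = TRUE,
    predict = function(theta, condition) {
      as.numeric(condition$G %*% theta)
    },
    jacobian = function(theta, condition) {
      list(pred = as.numeric(condition$G %*% theta), G = condition$G)
    }), class = "mirnn_model")
}

linear_dataset <- function(n_theta, n_y, n_cond, theta_true, sigma,
                           seed = 1L) {
  set.seed(seed)
  conditions <- lapply(seq_len(n_cond), function(i) {
    list(G = matrix(rnorm(n_y * n_theta), n_y, n_theta))
  })
  observations <- lapply(conditions, function(cond) {
    as.numeric(cond$G %*% theta_true) +
      rnorm(n_y, sd = sqrt(rep_len(sigma, n_y)))
  })
  list(conditions = conditions, observations = observations)
}

# Closed-form ridge/Bayesian linear regression on a linear dataset.
ridge_posterior <- function(dataset, alpha, sigma, n_theta, n_y) {
  P <- diag(rep_len(alpha, n_theta), n_theta)
  b <- rep(0, n_theta)
  for (i in seq_along(dataset$conditions)) {
    G <- dataset$conditions[[i]]$G
    W <- diag(1 / rep_len(sigma, n_y), n_y)
    P <- P + t(G) %*% W %*% G
    b <- b + t(G) %*% W %*% dataset$observations[[i]]
  }
  list(mean = as.numeric(solve(P, b)), precision = P)
}

# Exact log marginal likelihood of a linear-Gaussian model.
linear_log_marginal <- function(dataset, alpha, sigma, n_theta, n_y) {
  Gs <- do.call(rbind, lapply(dataset$conditions, `[[`, "G"))
  ys <- unlist(dataset$observations)
  S <- Gs %*% diag(rep(1 / alpha, n_theta)) %*% t(Gs) +
    diag(rep_len(sigma, n_y * length(dataset$conditions)))
  R <- chol((S + t(S)) / 2)
  z <- forwardsolve(t(R), ys)
  -0.5 * length(ys) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Small random SPD matrix.
random_spd <- function(n, seed = 1L, jitter = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + jitter * diag(n)
}
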