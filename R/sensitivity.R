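#' Sensitivity matrix of a MiRNN rollout
#'
#' Computes the Jacobian G of the training-mode rolled-out outputs of one
#' condition with respect to the flattened parameter vector, by exact
#' forward-mode sensitivity propagation through the recurrence (the chain
#' rule applied step by step; exact to machine precision, no finite
#' differencing). Rows are ordered time-major: the `n_y` outputs of step 1,
#' then of step 2, and so on; columns follow the [flatten_params()] layout.
#'
#' The absent-species mask is treated as locally constant, so rows
#' belonging to a masked species are exactly zero: the constraint removes
#' any parameter dependence of that output.
#'
#' @param theta flattened parameter vector.
#' @param condition a [mirnn_condition()] on the model's (scaled) units.
#' @param dims the [mirnn_dims()].
#' @param constrained disable for the unconstrained-RNN ablation.
#' @param leaky_slope LeakyReLU negative slope.
#' @return List with `pred`, the `n_tau x n_y` training-mode output matrix,
#'   and `G`, the `(n_tau * n_y) x n_theta` sensitivity matrix.
#' @export
mirnn_sensitivity <- function(theta, condition, dims, constrained = TRUE,
                              leaky_slope = 0.01) {
  off <- param_offsets(dims)
  n_theta <- off$total
  stopifnot(length(theta) == n_theta)
  params <- unflatten_params(theta, dims)
  n_h <- dims$n_h; n_in <- dims$n_in; n_y <- dims$n_y
  n_s <- dims$n_s; n_u <- dims$n_u
  n_tau <- length(condition$times) - 1L
  o_whh <- off$offsets[["W_hh"]]; o_bhh <- off$offsets[["b_hh"]]
  o_wih <- off$offsets[["W_ih"]]; o_who <- off$offsets[["W_ho"]]
  o_bho <- off$offsets[["b_ho"]]; o_h0 <- off$offsets[["h_0"]]
  W_ih_y <- t(params$W_ih[seq_len(n_y), , drop = FALSE])   # n_h x n_y

  h <- params$h_0
  Dh <- matrix(0, n_h, n_theta)
  Dh[cbind(seq_len(n_h), o_h0 + seq_len(n_h))] <- 1
  s_prev <- condition$s0
  m_prev <- condition$m0
  Dy_prev <- matrix(0, n_y, n_theta)

  pred <- matrix(NA_real_, n_tau, n_y)
  G <- matrix(0, n_tau * n_y, n_theta)
  rows_h <- seq_len(n_h); rows_y <- seq_len(n_y)

  for (t in seq_len(n_tau)) {
    u_prev <- condition$controls[t, ]
    u_curr <- condition$controls[t + 1L, ]
    x <- c(s_prev, m_prev, u_prev, u_curr)
    a <- as.numeric(params$W_hh %*% h + crossprod(params$W_ih, x) +
                      params$b_hh)
    # chain-rule terms through the previous latent state and fed-back
    # outputs, then the direct dependence of a on W_hh, W_ih, b_hh
    Da <- params$W_hh %*% Dh + W_ih_y %*% Dy_prev
    for (j in seq_len(n_h)) {
      cols <- o_whh + (j - 1L) * n_h + rows_h
      idx <- cbind(rows_h, cols)
      Da[idx] <- Da[idx] + h[j]
    }
    Da[cbind(rows_h, o_bhh + rows_h)] <- Da[cbind(rows_h, o_bhh + rows_h)] + 1
    for (k in seq_len(n_h)) {
      cols <- o_wih + (k - 1L) * n_in + seq_len(n_in)
      Da[k, cols] <- Da[k, cols] + x
    }
    act <- a > 0
    dact <- act + leaky_slope * !act
    h <- a * dact          # LeakyReLU(a)
    Dh <- Da * dact        # row k scaled by the activation derivative
    o <- as.numeric(crossprod(params$W_ho, h) + params$b_ho)
    Do <- crossprod(params$W_ho, Dh)
    for (y in seq_len(n_y)) {
      cols <- o_who + (y - 1L) * n_h + rows_h
      Do[y, cols] <- Do[y, cols] + h
    }
    Do[cbind(rows_y, o_bho + rows_y)] <- Do[cbind(rows_y, o_bho + rows_y)] + 1
    if (constrained) {
      mask <- s_prev > 0
      o[seq_len(n_s)] <- o[seq_len(n_s)] * mask
      Do[seq_len(n_s)[!mask], ] <- 0
    }
    pred[t, ] <- o
    G[(t - 1L) * n_y + rows_y, ] <- Do
    s_prev <- o[seq_len(n_s)]
    m_prev <- if (dims$n_m > 0) o[(n_s + 1L):n_y] else numeric(0)
    Dy_prev <- Do
  }
  list(pred = pred, G = G)
}

#' Finite-difference sensitivity (independent cross-check)
#'
#' Central-difference approximation of the same Jacobian as
#' [mirnn_sensitivity()]; used to validate the analytic propagation, and
#' available as a fallback Jacobian mode.
#'
#' @inheritParams mirnn_sensitivity
#' @param step central-difference step on the (scaled) parameters.
#' @return As [mirnn_sensitivity()].
#' @export
mirnn_sensitivity_fd <- function(theta, condition, dims,
                                 constrained = TRUE, leaky_slope = 0.01,
                                 step = 1e-6) {
  f <- function(th) {
    as.vector(t(rollout_outputs(th, condition, dims, constrained,
                                leaky_slope)))
  }
  base <- f(theta)
  G <- matrix(0, length(base), length(theta))
  for (j in seq_along(theta)) {
    ej <- theta; ej[j] <- ej[j] + step
    mj <- theta; mj[j] <- mj[j] - step
    G[, j] <- (f(ej) - f(mj)) / (2 * step)
  }
  pred <- matrix(base, length(condition$times) - 1L, dims$n_y,
                 byrow = TRUE)
  list(pred = pred, G = G)
}

#' Model interface consumed by the Bayesian machinery
#'
#' The MAP/Laplace/EIG layer is model-agnostic: it only needs the number
#' of parameters, a prediction function and a Jacobian function. This
#' constructor packages a MiRNN as such an interface; test suites use the
#' same shape to plug in linear surrogate models with closed-form
#' posteriors.
#'
#' @param dims a [mirnn_dims()].
#' @param constrained whether the absent-species mask is active.
#' @param leaky_slope LeakyReLU negative slope.
#' @return List of class `mirnn_model` with elements `n_theta`,
#'   `predict(theta, condition)` returning the stacked output vector
#'   (time-major), `jacobian(theta, condition)` returning
#'   `list(pred, G)` with `pred` stacked the same way, `n_y`, and `dims`.
#' @export
mirnn_model <- function(dims, constrained = TRUE, leaky_slope = 0.01) {
  force(dims); force(constrained); force(leaky_slope)
  structure(list(
    n_theta = count_params(dims),
    n_y = dims$n_y,
    dims = dims,
    constrained = constrained,
    predict = function(theta, condition) {
      as.vector(t(rollout_outputs(theta, condition, dims, constrained,
                                  leaky_slope)))
    },
    jacobian = function(theta, condition) {
      sens <- mirnn_sensitivity(theta, condition, dims, constrained,
                                leaky_slope)
      list(pred = as.vector(t(sens$pred)), G = sens$G)
    }
  ), class = "mirnn_model")
}
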