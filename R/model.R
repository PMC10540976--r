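#' One MiRNN transition step
#'
#' Advances the community state by one sampling interval:
#' \deqn{h_t = \mathrm{LeakyReLU}(W_{hh} h_{t-1} + W_{ih}^T
#'   [s_{t-1}, m_{t-1}, u_{t-1}, u_t] + b_{hh})}
#' and raw output \eqn{o = W_{ho}^T h_t + b_{ho}}, split into species and
#' metabolite parts. The species part is multiplied elementwise by the
#' indicator \eqn{1[s_{t-1} > 0]}: a species absent at the previous step
#' stays exactly absent, which prevents autoregressive error from
#' spuriously re-seeding it. In inference mode a ReLU rectifies the full
#' output so abundances and concentrations are non-negative; in training
#' mode the rectifier is suppressed so that negative raw predictions incur
#' loss.
#'
#' @param params a `mirnn_params` object.
#' @param state list with elements `s`, `m`, `h` (the community state).
#' @param u_prev,u_curr control-input vectors at the previous and current
#'   step (length `n_u`; may be length 0).
#' @param mode `"inference"` (rectified outputs) or `"training"`
#'   (unrectified).
#' @param constrained set `FALSE` to disable the absent-species mask (the
#'   unconstrained-RNN ablation).
#' @param leaky_slope negative slope of the LeakyReLU hidden activation.
#' @return Updated state list with elements `s`, `m`, `h`.
#' @export
mirnn_step <- function(params, state, u_prev = numeric(0),
                       u_curr = numeric(0),
                       mode = c("inference", "training"),
                       constrained = TRUE, leaky_slope = 0.01) {
  mode <- match.arg(mode)
  dims <- attr(params, "dims")
  x <- c(state$s, state$m, u_prev, u_curr)
  if (length(x) != dims$n_in) {
    stop(sprintf("step input has length %d, expected %d",
                 length(x), dims$n_in))
  }
  if (any(!is.finite(x)) || any(!is.finite(state$h))) {
    stop("non-finite state or inputs")
  }
  a <- as.numeric(params$W_hh %*% state$h + crossprod(params$W_ih, x) +
                    params$b_hh)
  h <- leaky_relu(a, leaky_slope)
  o <- as.numeric(crossprod(params$W_ho, h) + params$b_ho)
  s <- o[seq_len(dims$n_s)]
  m <- if (dims$n_m > 0) o[(dims$n_s + 1L):dims$n_y] else numeric(0)
  if (constrained) s <- s * (state$s > 0)
  if (mode == "inference") {
    s <- pmax(s, 0)
    m <- pmax(m, 0)
  }
  list(s = s, m = m, h = h)
}

leaky_relu <- function(x, slope = 0.01) {
  pos <- x > 0
  x * (pos + slope * !pos)
}

#' Autoregressive trajectory prediction
#'
#' Rolls the MiRNN forward over all `n_tau` steps of a condition, feeding
#' each step's own output back as the next step's input, with the latent
#' state initialised to the learned `h_0`.
#'
#' @inheritParams mirnn_step
#' @param condition a [mirnn_condition()] on the model's (scaled) units.
#' @return An object of class `mirnn_trajectory`: list with `times`, the
#'   `(n_tau+1) x n_s` species matrix `s`, the `(n_tau+1) x n_m`
#'   metabolite matrix `m` (each including the initial row), and the
#'   stacked `n_tau x n_y` output matrix `y` for steps `t = 1..n_tau`.
#' @export
predict_trajectory <- function(params, condition,
                               mode = c("inference", "training"),
                               constrained = TRUE, leaky_slope = 0.01) {
  mode <- match.arg(mode)
  dims <- attr(params, "dims")
  n_tau <- length(condition$times) - 1L
  state <- list(s = condition$s0, m = condition$m0, h = params$h_0)
  S <- matrix(NA_real_, n_tau + 1L, dims$n_s)
  M <- matrix(NA_real_, n_tau + 1L, dims$n_m)
  S[1L, ] <- condition$s0
  if (dims$n_m > 0) M[1L, ] <- condition$m0
  for (t in seq_len(n_tau)) {
    u_prev <- condition$controls[t, ]
    u_curr <- condition$controls[t + 1L, ]
    state <- mirnn_step(params, state, u_prev, u_curr, mode = mode,
                        constrained = constrained,
                        leaky_slope = leaky_slope)
    S[t + 1L, ] <- state$s
    if (dims$n_m > 0) M[t + 1L, ] <- state$m
  }
  Y <- cbind(S[-1L, , drop = FALSE], M[-1L, , drop = FALSE])
  structure(list(times = condition$times, s = S, m = M, y = Y),
            class = "mirnn_trajectory")
}

# Rollout of training-mode outputs from a flattened parameter vector;
# the (n_tau x n_y) matrix the likelihood compares to observations.
rollout_outputs <- function(theta, condition, dims, constrained = TRUE,
                            leaky_slope = 0.01) {
  params <- unflatten_params(theta, dims)
  predict_trajectory(params, condition, mode = "training",
                     constrained = constrained,
                     leaky_slope = leaky_slope)$y
}
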