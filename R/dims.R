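#' Model dimensions
#'
#' Bundle of the integer dimensions that fully determine the shape of a
#' MiRNN: species count `n_s`, metabolite count `n_m`, control-input count
#' `n_u`, latent-state size `n_h` and the number of autoregressive
#' prediction steps `n_tau`. The observed-output size `n_y = n_s + n_m` is
#' derived, never supplied.
#'
#' @param n_s number of species (>= 1).
#' @param n_m number of metabolites (>= 0).
#' @param n_u number of control inputs (>= 0); use 0 for batch-culture
#'   settings with no manipulable inputs.
#' @param n_h latent-state (hidden) dimension (>= 1). Larger values
#'   increase model flexibility.
#' @param n_tau number of prediction steps, i.e. observations are taken at
#'   `n_tau + 1` uniformly spaced times including the initial condition.
#' @return An object of class `mirnn_dims`.
#' @examples
#' d <- mirnn_dims(n_s = 25, n_m = 4, n_u = 0, n_h = 16)
#' count_params(d)
#' @export
mirnn_dims <- function(n_s, n_m = 0L, n_u = 0L, n_h = 16L, n_tau = 4L) {
  vals <- c(n_s = n_s, n_m = n_m, n_u = n_u, n_h = n_h, n_tau = n_tau)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    stop("all dimensions must be non-negative integers")
  }
  if (n_s < 1) stop("n_s must be >= 1")
  if (n_h < 1) stop("n_h must be >= 1")
  structure(
    list(n_s = as.integer(n_s), n_m = as.integer(n_m),
         n_u = as.integer(n_u), n_h = as.integer(n_h),
         n_tau = as.integer(n_tau),
         n_y = as.integer(n_s + n_m),
         n_in = as.integer(n_s + n_m + 2L * n_u)),
    class = "mirnn_dims"
  )
}

#' @export
print.mirnn_dims <- function(x, ...) {
  cat(sprintf(
    "MiRNN dimensions: %d species, %d metabolites, %d controls, %d hidden, %d steps (n_theta = %d)\n",
    x$n_s, x$n_m, x$n_u, x$n_h, x$n_tau, count_params(x)))
  invisible(x)
}

#' Number of free parameters of a MiRNN
#'
#' The parameter set is theta = \{W_hh, b_hh, W_ih, W_ho, b_ho, h_0\}; the
#' count is `n_h^2 + n_h + (n_s + n_m + 2 n_u) n_h + n_h n_y + n_y + n_h`.
#'
#' @param dims a [mirnn_dims()] object.
#' @return Integer parameter count.
#' @export
count_params <- function(dims) {
  stopifnot(inherits(dims, "mirnn_dims"))
  with(dims, n_h * n_h + n_h + n_in * n_h + n_h * n_y + n_y + n_h)
}
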