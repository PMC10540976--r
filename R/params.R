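#' Initialize MiRNN parameters
#'
#' Draws a reproducible small random initialization: every weight, bias and
#' the shared initial latent vector `h_0` is Normal(0, scale^2). Small
#' weights keep the initial rollout near zero, inside the linear region of
#' the LeakyReLU, which stabilises the first Newton steps.
#'
#' @param dims a [mirnn_dims()] object.
#' @param seed integer seed; identical seeds give bitwise-identical
#'   parameters.
#' @param scale standard deviation of the initial draws.
#' @return An object of class `mirnn_params` with elements `W_hh`
#'   (`n_h x n_h`), `b_hh` (`n_h`), `W_ih` (`n_in x n_h`), `W_ho`
#'   (`n_h x n_y`), `b_ho` (`n_y`) and `h_0` (`n_h`).
#' @export
init_params <- function(dims, seed = 0L, scale = 0.1) {
  stopifnot(inherits(dims, "mirnn_dims"))
  params <- with_seed(seed, {
    draw <- function(n) stats::rnorm(n, sd = scale)
    list(
      W_hh = matrix(draw(dims$n_h * dims$n_h), dims$n_h, dims$n_h),
      b_hh = draw(dims$n_h),
      W_ih = matrix(draw(dims$n_in * dims$n_h), dims$n_in, dims$n_h),
      W_ho = matrix(draw(dims$n_h * dims$n_y), dims$n_h, dims$n_y),
      b_ho = draw(dims$n_y),
      h_0  = draw(dims$n_h)
    )
  })
  new_mirnn_params(params, dims)
}

new_mirnn_params <- function(params, dims) {
  structure(params, dims = dims, class = "mirnn_params")
}

#' Flatten MiRNN parameters to a vector
#'
#' Concatenates the parameter blocks in the fixed order W_hh, b_hh, W_ih,
#' W_ho, b_ho, h_0 (matrices column-major). [unflatten_params()] inverts
#' the layout exactly, and the length always equals [count_params()].
#'
#' @param params a `mirnn_params` object.
#' @return Numeric vector of length `count_params(dims)`.
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "mirnn_params"))
  c(as.vector(params$W_hh), params$b_hh, as.vector(params$W_ih),
    as.vector(params$W_ho), params$b_ho, params$h_0)
}

#' @rdname flatten_params
#' @param theta numeric vector as produced by [flatten_params()].
#' @param dims the [mirnn_dims()] the vector belongs to.
#' @export
unflatten_params <- function(theta, dims) {
  stopifnot(inherits(dims, "mirnn_dims"))
  if (length(theta) != count_params(dims)) {
    stop(sprintf("theta has length %d, expected %d",
                 length(theta), count_params(dims)))
  }
  n_h <- dims$n_h; n_in <- dims$n_in; n_y <- dims$n_y
  pos <- 0L
  take <- function(n) {
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  params <- list(
    W_hh = matrix(take(n_h * n_h), n_h, n_h),
    b_hh = take(n_h),
    W_ih = matrix(take(n_in * n_h), n_in, n_h),
    W_ho = matrix(take(n_h * n_y), n_h, n_y),
    b_ho = take(n_y),
    h_0  = take(n_h)
  )
  new_mirnn_params(params, dims)
}

# Offsets of each block within the flattened vector (used by the exact
# forward-mode sensitivity propagation).
param_offsets <- function(dims) {
  n_h <- dims$n_h; n_in <- dims$n_in; n_y <- dims$n_y
  sizes <- c(W_hh = n_h * n_h, b_hh = n_h, W_ih = n_in * n_h,
             W_ho = n_h * n_y, b_ho = n_y, h_0 = n_h)
  offs <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  list(offsets = offs, sizes = sizes, total = sum(sizes))
}

#' @export
print.mirnn_params <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("MiRNN parameters (%d values) for ", count_params(d)))
  print(d)
  invisible(x)
}
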