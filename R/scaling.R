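#' Max-based data scaling
#'
#' Divides every feature by its maximum over the training data so that all
#' inputs lie in \[0, 1\]. Unlike standardization (subtract mean, divide by
#' standard deviation), dividing by the maximum maps zero to zero exactly,
#' which is what allows the absent-species constraint and the rectified
#' outputs to operate on scaled data. Features whose training maximum is 0
#' are constant-zero; they are given divisor 1 so they pass through
#' unchanged.
#'
#' @param dataset a [mirnn_dataset()] (the training split only).
#' @param scale_controls whether control inputs are scaled by their maxima
#'   as well (default `TRUE`).
#' @return An object of class `mirnn_scaling` with fields `y_max`
#'   (length `n_y`) and `u_max` (length `n_u`).
#' @export
fit_scaling <- function(dataset, scale_controls = TRUE) {
  stopifnot(inherits(dataset, "mirnn_dataset"))
  if (length(dataset) == 0) stop("dataset is empty")
  dims <- dataset$dims
  y_max <- rep(0, dims$n_y)
  u_max <- rep(0, dims$n_u)
  for (i in seq_along(dataset$conditions)) {
    cond <- dataset$conditions[[i]]
    y0 <- c(cond$s0, cond$m0)
    obs <- dataset$observations[[i]]
    vals <- rbind(matrix(y0, 1), obs)
    if (any(vals < 0, na.rm = TRUE)) {
      stop("negative raw measurements are not valid abundances/concentrations")
    }
    y_max <- pmax(y_max, apply(vals, 2, max, na.rm = TRUE))
    if (dims$n_u > 0) {
      if (any(cond$controls < 0)) stop("negative control inputs")
      u_max <- pmax(u_max, apply(cond$controls, 2, max))
    }
  }
  if (!scale_controls) u_max <- rep(1, dims$n_u)
  structure(list(y_max = y_max, u_max = u_max,
                 scale_controls = scale_controls),
            class = "mirnn_scaling")
}

divisors <- function(m) ifelse(m > 0, m, 1)

#' Apply or invert a scaling transform
#'
#' `scale_outputs()` and `unscale_outputs()` act on output matrices or
#' vectors (columns ordered species then metabolites); `scale_condition()`
#' scales a condition's initial state and controls; `scale_dataset()`
#' scales every condition and observation.
#'
#' @param y numeric matrix or vector of outputs in original units.
#' @param scaling a `mirnn_scaling` from [fit_scaling()].
#' @return Object of the same shape on the scaled (or original) scale.
#' @export
scale_outputs <- function(y, scaling) {
  d <- divisors(scaling$y_max)
  if (is.matrix(y)) sweep(y, 2, d, "/") else y / d
}

#' @rdname scale_outputs
#' @export
unscale_outputs <- function(y, scaling) {
  d <- divisors(scaling$y_max)
  if (is.matrix(y)) sweep(y, 2, d, "*") else y * d
}

#' @rdname scale_outputs
#' @param condition a [mirnn_condition()].
#' @export
scale_condition <- function(condition, scaling) {
  n_s <- length(condition$s0)
  dy <- divisors(scaling$y_max)
  du <- divisors(scaling$u_max)
  condition$s0 <- condition$s0 / dy[seq_len(n_s)]
  if (length(condition$m0) > 0) {
    condition$m0 <- condition$m0 / dy[(n_s + 1L):length(dy)]
  }
  if (ncol(condition$controls) > 0) {
    condition$controls <- sweep(condition$controls, 2, du, "/")
  }
  condition
}

#' @rdname scale_outputs
#' @param dataset a [mirnn_dataset()].
#' @export
scale_dataset <- function(dataset, scaling) {
  dataset$conditions <- lapply(dataset$conditions, scale_condition, scaling)
  dataset$observations <- lapply(dataset$observations, function(obs) {
    if (is.null(obs)) NULL else scale_outputs(obs, scaling)
  })
  dataset
}
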