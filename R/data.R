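#' Experimental conditions and datasets
#'
#' An experimental condition bundles the design variables of one
#' experiment: the initial species abundances `s0`, initial metabolite
#' concentrations `m0`, the control trajectory (one row per sampling time,
#' so `n_tau + 1` rows) and the uniformly spaced sampling times in hours.
#'
#' @param s0 numeric vector of initial species abundances (length `n_s`).
#' @param m0 numeric vector of initial metabolite concentrations.
#' @param controls numeric matrix with `length(times)` rows and `n_u`
#'   columns; use a zero-column matrix when there are no controls.
#' @param times strictly increasing, uniformly spaced sampling times.
#' @param id optional identifier carried through file round-trips.
#' @return An object of class `mirnn_condition`.
#' @export
mirnn_condition <- function(s0, m0 = numeric(0), controls = NULL,
                            times = NULL, id = NULL) {
  s0 <- as.numeric(s0); m0 <- as.numeric(m0)
  if (is.null(times)) times <- seq(0, 4)
  times <- as.numeric(times)
  if (length(times) < 2) stop("need at least two sampling times")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt))) {
    stop("times must be uniformly spaced (discrete-time model contract)")
  }
  if (is.null(controls)) {
    controls <- matrix(0, length(times), 0)
  }
  controls <- as.matrix(controls)
  if (nrow(controls) != length(times)) {
    stop("controls must have one row per sampling time")
  }
  structure(list(s0 = s0, m0 = m0, controls = controls, times = times,
                 id = id),
            class = "mirnn_condition")
}

#' Bundle conditions with observations into a dataset
#'
#' Observations for a condition are a matrix with `n_tau` rows (times
#' `t = 1..n_tau`; the initial state is part of the condition, not an
#' observation) and `n_s + n_m` columns ordered species then metabolites.
#'
#' @param conditions list of [mirnn_condition()] objects.
#' @param observations list of numeric matrices, one per condition.
#' @param dims the [mirnn_dims()] describing the variables.
#' @return An object of class `mirnn_dataset`.
#' @export
mirnn_dataset <- function(conditions, observations, dims) {
  stopifnot(inherits(dims, "mirnn_dims"))
  if (length(conditions) != length(observations)) {
    stop("conditions and observations must have equal length")
  }
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    obs <- observations[[i]]
    if (length(cond$s0) != dims$n_s || length(cond$m0) != dims$n_m) {
      stop(sprintf("condition %d state dimensions do not match dims", i))
    }
    if (ncol(cond$controls) != dims$n_u) {
      stop(sprintf("condition %d has %d control columns, expected %d",
                   i, ncol(cond$controls), dims$n_u))
    }
    if (!is.null(obs) &&
        (nrow(obs) != length(cond$times) - 1L || ncol(obs) != dims$n_y)) {
      stop(sprintf("observations %d must be (n_tau x n_y) = (%d x %d)",
                   i, length(cond$times) - 1L, dims$n_y))
    }
  }
  structure(list(conditions = conditions, observations = observations,
                 dims = dims),
            class = "mirnn_dataset")
}

#' @export
length.mirnn_dataset <- function(x) length(x$conditions)

#' Subset a dataset by condition index
#' @param x a `mirnn_dataset`.
#' @param idx integer indices of conditions to keep.
#' @return A `mirnn_dataset` with the selected conditions.
#' @export
subset_dataset <- function(x, idx) {
  mirnn_dataset(x$conditions[idx], x$observations[idx], x$dims)
}

#' Concatenate datasets over conditions
#' @param ... `mirnn_dataset` objects sharing the same dimensions.
#' @return The combined `mirnn_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  ds <- ds[!vapply(ds, is.null, logical(1))]
  stopifnot(length(ds) >= 1)
  mirnn_dataset(
    do.call(c, lapply(ds, `[[`, "conditions")),
    do.call(c, lapply(ds, `[[`, "observations")),
    ds[[1]]$dims
  )
}

#' @export
print.mirnn_dataset <- function(x, ...) {
  cat(sprintf("MiRNN dataset: %d conditions, %d species, %d metabolites, %d controls\n",
              length(x$conditions), x$dims$n_s, x$dims$n_m, x$dims$n_u))
  invisible(x)
}
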