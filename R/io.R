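#' @title File formats
#' @description
#' Trajectories travel as long-format delimited text with columns
#' `condition_id, time_h, variable_kind, variable_name, value`
#' (`variable_kind` one of species/metabolite/control); parameters and
#' posteriors as JSON with a dimensions header. No binary formats.
#' @name io
NULL

var_names <- function(prefix, n) sprintf("%s%d", prefix, seq_len(n))

#' Convert a dataset to the long trajectory table
#'
#' Initial states appear at the first time point; observations at the
#' later time points; controls at every time point.
#'
#' @param dataset a [mirnn_dataset()].
#' @return data.frame with columns `condition_id`, `time_h`,
#'   `variable_kind`, `variable_name`, `value`.
#' @export
dataset_to_long <- function(dataset) {
  dims <- dataset$dims
  sp <- var_names("s", dims$n_s)
  mb <- var_names("m", dims$n_m)
  ct <- var_names("u", dims$n_u)
  rows <- lapply(seq_along(dataset$conditions), function(i) {
    cond <- dataset$conditions[[i]]
    id <- if (is.null(cond$id)) sprintf("condition_%03d", i) else cond$id
    obs <- dataset$observations[[i]]
    vals <- rbind(c(cond$s0, cond$m0), obs)
    out <- list()
    for (t in seq_along(cond$times)) {
      out[[length(out) + 1L]] <- data.frame(
        condition_id = id, time_h = cond$times[t],
        variable_kind = c(rep("species", dims$n_s),
                          rep("metabolite", dims$n_m)),
        variable_name = c(sp, mb), value = vals[t, ])
      if (dims$n_u > 0) {
        out[[length(out) + 1L]] <- data.frame(
          condition_id = id, time_h = cond$times[t],
          variable_kind = "control", variable_name = ct,
          value = cond$controls[t, ])
      }
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild a dataset from a long trajectory table
#'
#' Inverts [dataset_to_long()]. Validates uniform time spacing per
#' condition (the discrete-time model contract) and consistent variables
#' across conditions.
#'
#' @param df data.frame as produced by [dataset_to_long()].
#' @param n_h hidden size recorded in the resulting dimensions object.
#' @return A [mirnn_dataset()].
#' @export
long_to_dataset <- function(df, n_h = 16L) {
  need <- c("condition_id", "time_h", "variable_kind", "variable_name",
            "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  ids <- unique(df$condition_id)
  sp <- sort_by_index(unique(df$variable_name[df$variable_kind == "species"]))
  mb <- sort_by_index(unique(df$variable_name[df$variable_kind == "metabolite"]))
  ct <- sort_by_index(unique(df$variable_name[df$variable_kind == "control"]))
  n_s <- length(sp); n_m <- length(mb); n_u <- length(ct)
  conditions <- list(); observations <- list()
  n_tau <- NULL
  for (id in ids) {
    sub <- df[df$condition_id == id, ]
    times <- sort(unique(sub$time_h))
    dt <- diff(times)
    if (length(dt) < 1 || max(abs(dt - dt[1])) > 1e-8 * max(abs(dt))) {
      stop(sprintf("condition %s: times not uniformly spaced", id))
    }
    if (is.null(n_tau)) n_tau <- length(times) - 1L
    grab <- function(kind, namevec) {
      out <- matrix(NA_real_, length(times), length(namevec))
      k <- sub[sub$variable_kind == kind, ]
      for (r in seq_len(nrow(k))) {
        ti <- match(k$time_h[r], times)
        vi <- match(k$variable_name[r], namevec)
        out[ti, vi] <- k$value[r]
      }
      out
    }
    Y <- cbind(grab("species", sp),
               if (n_m > 0) grab("metabolite", mb))
    U <- if (n_u > 0) grab("control", ct) else matrix(0, length(times), 0)
    conditions[[length(conditions) + 1L]] <- mirnn_condition(
      s0 = Y[1, seq_len(n_s)],
      m0 = if (n_m > 0) Y[1, (n_s + 1):(n_s + n_m)] else numeric(0),
      controls = U, times = times, id = id)
    observations[[length(observations) + 1L]] <-
      Y[-1, , drop = FALSE]
  }
  dims <- mirnn_dims(n_s, n_m, n_u, n_h, n_tau)
  mirnn_dataset(conditions, observations, dims)
}

sort_by_index <- function(x) {
  if (length(x) == 0) return(x)
  x[order(as.integer(gsub("[^0-9]", "", x)))]
}

#' Read and write long-format trajectory files
#'
#' @param dataset a [mirnn_dataset()].
#' @param path file path (CSV with mandatory header).
#' @export
write_trajectories <- function(dataset, path) {
  utils::write.csv(dataset_to_long(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @inheritParams long_to_dataset
#' @export
read_trajectories <- function(path, n_h = 16L) {
  long_to_dataset(utils::read.csv(path, stringsAsFactors = FALSE), n_h)
}

#' Serialize parameters to JSON (flat vector plus dimensions header)
#'
#' @param params a `mirnn_params` object.
#' @param path output path.
#' @export
write_params <- function(params, path) {
  dims <- attr(params, "dims")
  jsonlite::write_json(list(
    dims = dims[c("n_s", "n_m", "n_u", "n_h", "n_tau")],
    theta = flatten_params(params)), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- do.call(mirnn_dims, as.list(obj$dims))
  unflatten_params(as.numeric(obj$theta), dims)
}

#' Serialize a Laplace posterior to JSON
#'
#' Stores the MAP vector, dense Hessian, hyperparameters, scaling maxima
#' and dimensions header; [read_posterior()] rebuilds the `mirnn_model`
#' interface from the header.
#'
#' @param posterior a `mirnn_posterior` whose model is a [mirnn_model()].
#' @param path output path.
#' @export
write_posterior <- function(posterior, path) {
  dims <- posterior$model$dims
  jsonlite::write_json(list(
    dims = dims[c("n_s", "n_m", "n_u", "n_h", "n_tau")],
    constrained = posterior$model$constrained,
    theta_map = posterior$theta_map,
    hessian = posterior$hessian,
    alpha = posterior$alpha,
    sigma_y = posterior$sigma_y,
    scaling = if (is.null(posterior$scaling)) NULL else
      posterior$scaling[c("y_max", "u_max", "scale_controls")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- do.call(mirnn_dims, as.list(obj$dims))
  model <- mirnn_model(dims, constrained = isTRUE(obj$constrained))
  scaling <- if (!is.null(obj$scaling)) {
    structure(list(y_max = as.numeric(obj$scaling$y_max),
                   u_max = as.numeric(obj$scaling$u_max),
                   scale_controls = isTRUE(obj$scaling$scale_controls)),
              class = "mirnn_scaling")
  } else NULL
  structure(list(theta_map = as.numeric(obj$theta_map),
                 hessian = as.matrix(obj$hessian),
                 alpha = as.numeric(obj$alpha),
                 sigma_y = as.numeric(obj$sigma_y),
                 scaling = scaling, model = model,
                 fit = list(converged = NA, grad_norm = NA_real_)),
            class = "mirnn_posterior")
}
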