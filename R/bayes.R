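#' @title MAP estimation and Laplace-approximate posteriors
#' @description
#' The training layer is model-agnostic: it consumes any model interface
#' with `n_theta`, `predict(theta, condition)` and
#' `jacobian(theta, condition)` (see [mirnn_model()]), a dataset with
#' `$conditions` and `$observations`, a Gaussian prior
#' `theta ~ N(0, alpha^-1 I)` and a Gaussian observation noise covariance
#' `sigma_y` (diagonal vector by default, full matrix optional).
#' @name bayes
NULL

obs_vector <- function(obs) {
  if (is.matrix(obs)) as.vector(t(obs)) else as.numeric(obs)
}

# 0.5 * r' Sigma^-1 r for one condition's stacked residual.
quad_noise <- function(r, sigma_y, n_y) {
  if (sigma_is_diagonal(sigma_y)) {
    v <- rep_len(rep(as.numeric(sigma_y), length.out = n_y),
                 length(r))
    0.5 * sum(r^2 / v)
  } else {
    S <- expand_sigma(sigma_y, length(r))
    0.5 * sum(r * solve_spd(S, r))
  }
}

# Sigma^-1 G for one condition (rows time-major, tiled n_y blocks).
prec_times <- function(G, sigma_y, n_y) {
  if (sigma_is_diagonal(sigma_y)) {
    v <- rep_len(rep(as.numeric(sigma_y), length.out = n_y), nrow(G))
    G / v
  } else {
    S <- expand_sigma(sigma_y, nrow(G))
    solve_spd(S, G)
  }
}

prior_precision <- function(alpha, n_theta) {
  rep_len(as.numeric(alpha), n_theta)
}

#' Negative log posterior (MAP objective)
#'
#' One half the noise-weighted sum of squared residuals over all
#' conditions and time points, computed with training-mode (unrectified)
#' model outputs, plus the Gaussian prior penalty
#' `0.5 * sum(alpha * theta^2)`. Constant normalisation terms are
#' excluded; [log_evidence()] restores them.
#'
#' @param theta flattened parameter vector.
#' @param model a model interface such as [mirnn_model()].
#' @param dataset object with `$conditions` and `$observations`.
#' @param alpha prior precision: scalar or vector of length `n_theta`.
#' @param sigma_y noise covariance: scalar or length-`n_y` vector of
#'   variances (diagonal), or an `n_y x n_y` matrix.
#' @return Scalar objective value.
#' @export
neg_log_posterior <- function(theta, model, dataset, alpha, sigma_y) {
  a <- prior_precision(alpha, model$n_theta)
  val <- 0.5 * sum(a * theta^2)
  for (i in seq_along(dataset$conditions)) {
    obs <- dataset$observations[[i]]
    if (is.null(obs)) next
    r <- obs_vector(obs) - model$predict(theta, dataset$conditions[[i]])
    val <- val + quad_noise(r, sigma_y, model$n_y)
  }
  val
}

#' Fit the MAP estimate by Gauss-Newton/Newton iteration
#'
#' Minimises [neg_log_posterior()] with damped Newton steps whose Hessian
#' is the Gauss-Newton approximation (prior precision plus
#' `sum(G' Sigma^-1 G)`), which is positive definite by construction and
#' so always yields descent directions. An Armijo backtracking line search
#' (c = 1e-4) globalises the iteration. Deterministic given the
#' initialisation.
#'
#' @inheritParams neg_log_posterior
#' @param init initial parameter vector (default all zero, the prior
#'   mode).
#' @param tol convergence tolerance on the gradient infinity-norm.
#' @param max_iter maximum Newton iterations.
#' @param n_restarts if > 1, additionally restarts from this many seeded
#'   random initialisations and keeps the lowest objective.
#' @param restart_seed seed for the restart draws.
#' @param quiet suppress the non-convergence warning.
#' @return List with `theta` (the MAP estimate), `objective`,
#'   `grad_norm`, `iterations` and logical `converged`. Non-convergence
#'   is flagged, never silent.
#' @export
fit_map <- function(model, dataset, alpha, sigma_y, init = NULL,
                    tol = 1e-5, max_iter = 500L, n_restarts = 1L,
                    restart_seed = 1L, quiet = FALSE) {
  n_theta <- model$n_theta
  inits <- list(if (is.null(init)) rep(0, n_theta) else as.numeric(init))
  if (n_restarts > 1L) {
    extra <- with_seed(restart_seed, lapply(seq_len(n_restarts - 1L),
      function(i) stats::rnorm(n_theta, sd = 0.1)))
    inits <- c(inits, extra)
  }
  best <- NULL
  for (ini in inits) {
    fit <- newton_gn(model, dataset, alpha, sigma_y, ini, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged && !quiet) {
    warning(sprintf(
      "MAP fit did not converge in %d iterations (grad norm %.3g > %.3g)",
      best$iterations, best$grad_norm, tol))
  }
  best
}

newton_gn <- function(model, dataset, alpha, sigma_y, theta, tol,
                      max_iter) {
  a <- prior_precision(alpha, model$n_theta)
  obj <- function(th) neg_log_posterior(th, model, dataset, alpha, sigma_y)
  f <- obj(theta)
  grad_norm <- Inf
  iter <- 0L
  converged <- FALSE
  stalled <- 0L
  repeat {
    grad <- a * theta
    H <- diag(a, model$n_theta)
    for (i in seq_along(dataset$conditions)) {
      obs <- dataset$observations[[i]]
      if (is.null(obs)) next
      jac <- model$jacobian(theta, dataset$conditions[[i]])
      r <- obs_vector(obs) - jac$pred
      PG <- prec_times(jac$G, sigma_y, model$n_y)
      grad <- grad - as.numeric(crossprod(PG, r))
      H <- H + crossprod(jac$G, PG)
    }
    grad_norm <- max(abs(grad))
    if (grad_norm <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    delta <- as.numeric(tryCatch(solve_spd(H, -grad),
                                 error = function(e) -grad / max(diag(H))))
    slope <- sum(grad * delta)
    step <- 1
    repeat {
      f_new <- obj(theta + step * delta)
      if (is.finite(f_new) && f_new <= f + 1e-4 * step * slope) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) break  # no descent possible: stationary up to noise
    # practical stop: negligible relative progress on the objective over
    # two consecutive accepted steps (kink-limited descent)
    stalled <- if (f - f_new < 1e-9 * (abs(f) + 1e-12)) stalled + 1L
               else 0L
    theta <- theta + step * delta
    f <- f_new
    iter <- iter + 1L
    if (stalled >= 2L) break
  }
  list(theta = theta, objective = f, grad_norm = grad_norm,
       iterations = iter, converged = converged)
}

#' Training initialization for a MiRNN fit
#'
#' Small random weights plus an output bias set to the per-output mean of
#' the scaled observations, so the initial rollout predicts positive
#' values near the data's centre of mass. Starting there keeps present
#' species above the absence threshold at the first step, which matters
#' because the constraint stops gradients flowing through species whose
#' fed-forward prediction has been masked to zero.
#'
#' @param dims a [mirnn_dims()] for the fitted model.
#' @param dataset the scaled training dataset.
#' @param seed seed for the random weight draws.
#' @param scale weight standard deviation.
#' @return Flattened parameter vector.
#' @export
training_init <- function(dims, dataset, seed = 1L, scale = 0.05) {
  p <- init_params(dims, seed = seed, scale = scale)
  obs <- do.call(rbind, dataset$observations)
  if (!is.null(obs) && nrow(obs) > 0) {
    p$b_ho <- pmax(colMeans(obs, na.rm = TRUE), 1e-3)
  }
  flatten_params(p)
}

#' Gauss-Newton Laplace Hessian of the negative log posterior
#'
#' `H = diag(alpha) + sum_i G_i' Sigma_y^-1 G_i`, evaluated at the MAP
#' estimate. Full rank (hence invertible) for any dataset because of the
#' diagonal prior precision term.
#'
#' @inheritParams neg_log_posterior
#' @param theta_map the fitted MAP parameter vector.
#' @return Symmetric positive-definite `n_theta x n_theta` matrix.
#' @export
laplace_hessian <- function(model, theta_map, dataset, alpha, sigma_y) {
  H <- diag(prior_precision(alpha, model$n_theta), model$n_theta)
  for (i in seq_along(dataset$conditions)) {
    if (is.null(dataset$observations[[i]])) next
    jac <- model$jacobian(theta_map, dataset$conditions[[i]])
    H <- H + crossprod(jac$G, prec_times(jac$G, sigma_y, model$n_y))
  }
  symmetrize(H)
}

#' Fit a full Laplace posterior
#'
#' Convenience wrapper running [fit_map()] then [laplace_hessian()].
#'
#' @inheritParams fit_map
#' @param scaling optional `mirnn_scaling` stored alongside (the data are
#'   assumed already scaled).
#' @return Object of class `mirnn_posterior` with fields `theta_map`,
#'   `hessian`, `alpha`, `sigma_y`, `scaling`, `model` and `fit`
#'   diagnostics.
#' @export
fit_posterior <- function(model, dataset, alpha, sigma_y, init = NULL,
                          tol = 1e-5, max_iter = 500L, scaling = NULL,
                          quiet = FALSE) {
  fit <- fit_map(model, dataset, alpha, sigma_y, init = init, tol = tol,
                 max_iter = max_iter, quiet = quiet)
  H <- laplace_hessian(model, fit$theta, dataset, alpha, sigma_y)
  structure(list(theta_map = fit$theta, hessian = H, alpha = alpha,
                 sigma_y = sigma_y, scaling = scaling, model = model,
                 fit = fit),
            class = "mirnn_posterior")
}

#' @export
print.mirnn_posterior <- function(x, ...) {
  cat(sprintf(
    "MiRNN Laplace posterior: %d parameters, converged = %s (grad %.2e)\n",
    length(x$theta_map), x$fit$converged, x$fit$grad_norm))
  invisible(x)
}

#' Linearized posterior predictive distribution
#'
#' Mean is the model prediction at the MAP estimate; covariance is the
#' aleatory noise covariance plus the linearized epistemic term
#' `G H^-1 G'`, so predictive uncertainty can never fall below the noise
#' floor.
#'
#' @param posterior a `mirnn_posterior` from [fit_posterior()].
#' @param condition the experimental condition to predict.
#' @return List of class `mirnn_predictive` with `mean` (stacked
#'   time-major output vector), `cov` (dense covariance including both
#'   uncertainty sources), and `cov_aleatory` (the noise part alone).
#' @export
posterior_predictive <- function(posterior, condition) {
  model <- posterior$model
  jac <- model$jacobian(posterior$theta_map, condition)
  HinvGt <- solve_spd(posterior$hessian, t(jac$G))
  sig <- posterior$sigma_y
  if (!is.matrix(sig)) {
    sig <- rep(rep_len(as.numeric(sig), model$n_y),
               nrow(jac$G) / model$n_y)
    S <- diag(sig, nrow(jac$G))
  } else {
    S <- expand_sigma(sig, nrow(jac$G))
  }
  structure(list(mean = jac$pred,
                 cov = symmetrize(S + jac$G %*% HinvGt),
                 cov_aleatory = S),
            class = "mirnn_predictive")
}

#' Log-likelihood of held-out observations
#'
#' Sums multivariate Gaussian log-densities of held-out observations under
#' each prediction's mean and either the condition-dependent predictive
#' covariance (aleatory plus epistemic) or the fixed noise covariance
#' alone. Comparing the two quantifies the value of the epistemic
#' uncertainty estimate.
#'
#' @param predictions list of `mirnn_predictive` objects.
#' @param observations list of observation matrices/vectors aligned with
#'   `predictions`.
#' @param covariance_mode `"predicted"` (full predictive covariance) or
#'   `"fixed"` (aleatory noise covariance only).
#' @return Scalar total log-likelihood.
#' @export
heldout_loglik <- function(predictions, observations,
                           covariance_mode = c("predicted", "fixed")) {
  covariance_mode <- match.arg(covariance_mode)
  stopifnot(length(predictions) == length(observations))
  total <- 0
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]
    y <- obs_vector(observations[[i]])
    cov <- if (covariance_mode == "predicted") p$cov else p$cov_aleatory
    total <- total + mvn_logdensity(y, p$mean, cov)
  }
  total
}

#' Laplace approximation of the log model evidence
#'
#' `log p(D | alpha, sigma_y)` approximated at the MAP estimate with all
#' Gaussian normalisation constants included, so on models linear in the
#' parameters it equals the exact linear-Gaussian marginal likelihood.
#'
#' @inheritParams laplace_hessian
#' @param hessian the Laplace Hessian at `theta_map` (computed if
#'   missing).
#' @return Scalar approximate log evidence.
#' @export
log_evidence <- function(model, dataset, alpha, sigma_y, theta_map,
                         hessian = NULL) {
  if (is.null(hessian)) {
    hessian <- laplace_hessian(model, theta_map, dataset, alpha, sigma_y)
  }
  a <- prior_precision(alpha, model$n_theta)
  e_map <- neg_log_posterior(theta_map, model, dataset, alpha, sigma_y)
  n_obs <- 0
  logdet_noise <- 0
  for (i in seq_along(dataset$conditions)) {
    obs <- dataset$observations[[i]]
    if (is.null(obs)) next
    n_i <- length(obs_vector(obs))
    n_obs <- n_obs + n_i
    if (sigma_is_diagonal(sigma_y)) {
      v <- rep_len(rep(as.numeric(sigma_y), length.out = model$n_y), n_i)
      logdet_noise <- logdet_noise + sum(log(v))
    } else {
      logdet_noise <- logdet_noise + logdet_spd(expand_sigma(sigma_y, n_i))
    }
  }
  -e_map - 0.5 * n_obs * log(2 * pi) - 0.5 * logdet_noise +
    0.5 * sum(log(a)) - 0.5 * logdet_spd(hessian)
}

#' Select the prior precision by evidence maximisation
#'
#' Fits the MAP estimate for each candidate prior precision on a grid
#' (warm-starting each fit from the previous solution) and returns the
#' value maximising the Laplace evidence approximation.
#'
#' @inheritParams fit_map
#' @param alpha_grid positive numeric vector of candidate precisions.
#' @return List with `alpha` (the argmax), `evidence` (named vector over
#'   the grid) and `theta` (MAP at the selected alpha).
#' @export
optimize_alpha <- function(model, dataset, sigma_y,
                           alpha_grid = 10^seq(-2, 3), init = NULL,
                           tol = 1e-5, max_iter = 200L) {
  if (length(alpha_grid) == 0) stop("alpha_grid is empty")
  ev <- numeric(length(alpha_grid))
  thetas <- vector("list", length(alpha_grid))
  theta <- init
  for (k in seq_along(alpha_grid)) {
    fit <- fit_map(model, dataset, alpha_grid[k], sigma_y, init = theta,
                   tol = tol, max_iter = max_iter, quiet = TRUE)
    theta <- fit$theta
    thetas[[k]] <- theta
    ev[k] <- log_evidence(model, dataset, alpha_grid[k], sigma_y, theta)
  }
  best <- which.max(ev)
  list(alpha = alpha_grid[best],
       evidence = stats::setNames(ev, signif(alpha_grid, 4)),
       theta = thetas[[best]])
}

#' Estimate the noise covariance by expectation-maximization
#'
#' Alternates (i) refitting the MAP estimate at the current noise
#' covariance with (ii) updating the diagonal noise variances from the
#' residual second moments plus the linearized epistemic variance
#' `diag(G H^-1 G')`, until the iteration budget is exhausted or the
#' relative change falls below `tol`. Variances are floored to keep the
#' covariance positive definite.
#'
#' @inheritParams fit_map
#' @param sigma_y_init initial diagonal noise variances (scalar or
#'   length-`n_y` vector).
#' @param n_em_iter maximum EM iterations.
#' @param tol relative-change stopping tolerance on the variances.
#' @param floor lower bound applied to each variance.
#' @return List with `sigma_y` (length-`n_y` variance vector),
#'   `theta_map`, `hessian`, `alpha` and the per-iteration `history`.
#' @export
estimate_sigma_y_em <- function(model, dataset, alpha, sigma_y_init = 0.01,
                                n_em_iter = 10L, tol = 1e-3,
                                floor = 1e-8, init = NULL,
                                max_iter = 200L) {
  n_y <- model$n_y
  sigma <- rep_len(as.numeric(sigma_y_init), n_y)
  theta <- init
  history <- list()
  fit <- NULL
  for (it in seq_len(n_em_iter)) {
    fit <- fit_map(model, dataset, alpha, sigma, init = theta,
                   max_iter = max_iter, quiet = TRUE)
    theta <- fit$theta
    H <- laplace_hessian(model, theta, dataset, alpha, sigma)
    ss <- rep(0, n_y)
    counts <- rep(0, n_y)
    for (i in seq_along(dataset$conditions)) {
      obs <- dataset$observations[[i]]
      if (is.null(obs)) next
      jac <- model$jacobian(theta, dataset$conditions[[i]])
      r <- obs_vector(obs) - jac$pred
      ep <- rowSums(jac$G * t(solve_spd(H, t(jac$G))))
      dim_idx <- ((seq_along(r) - 1L) %% n_y) + 1L
      for (j in seq_len(n_y)) {
        sel <- dim_idx == j
        ss[j] <- ss[j] + sum(r[sel]^2 + ep[sel])
        counts[j] <- counts[j] + sum(sel)
      }
    }
    if (any(counts == 0)) {
      warning("outputs with no observations: variance floored")
    }
    new_sigma <- ifelse(counts > 0, ss / pmax(counts, 1), floor)
    new_sigma <- pmax(new_sigma, floor)
    rel <- max(abs(new_sigma - sigma) / pmax(sigma, floor))
    history[[it]] <- new_sigma
    sigma <- new_sigma
    if (rel < tol) break
  }
  H <- laplace_hessian(model, theta, dataset, alpha, sigma)
  list(sigma_y = sigma, theta_map = theta, hessian = H, alpha = alpha,
       history = history, fit = fit)
}
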