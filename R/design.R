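#' @title Batch expected information gain and design selection
#' @description
#' The expected information gain (EIG) of a prospective batch of
#' conditions is the log-determinant increase of the Gauss-Newton
#' posterior precision. The direct form factorizes an
#' `n_theta x n_theta` matrix; the fast form rewrites it as a sum of
#' small `n_y x n_y` log-determinants whose running inverse is maintained
#' with Woodbury rank-updates, avoiding any large factorization beyond
#' the one reusable inversion of the current Hessian.
#' @name design
NULL

#' Direct (dense) expected information gain
#'
#' `ln det(H + sum_i G_i' Sigma_y^-1 G_i) - ln det(H)`. This is the
#' reference implementation used as the oracle for [eig_fast()].
#'
#' @param H current posterior precision (symmetric positive definite).
#' @param G_list list of sensitivity matrices, one per prospective
#'   condition (each `r_i x n_theta`).
#' @param sigma_y noise covariance (scalar, diagonal vector, or matrix);
#'   tiled across time points when `r_i` is a multiple of its size.
#' @param n_y output dimension per time point (defaults to the row count
#'   of `sigma_y` when a matrix, else the rows of each `G`).
#' @return Scalar EIG (non-negative).
#' @export
eig_direct <- function(H, G_list, sigma_y, n_y = NULL) {
  if (length(G_list) == 0) return(0)
  A <- H
  for (G in G_list) {
    ny <- block_size(sigma_y, n_y, nrow(G))
    A <- A + crossprod(G, prec_times(G, sigma_y, ny))
  }
  logdet_spd(A) - logdet_spd(H)
}

block_size <- function(sigma_y, n_y, n_rows) {
  if (!is.null(n_y)) return(n_y)
  if (is.matrix(sigma_y)) nrow(sigma_y) else n_rows
}

#' Fast expected information gain via Woodbury updates
#'
#' Computes the same quantity as [eig_direct()] as
#' `sum_i ln det(I + Sigma_y^-1 G_i A_{i-1}^-1 G_i')`, where
#' `A_0 = H` and each `A_i^-1` is obtained from `A_{i-1}^-1` by a
#' [woodbury_update()]. Only the initial inversion of `H` touches an
#' `n_theta x n_theta` factorization, and it can be precomputed once and
#' shared across many candidate evaluations via `H_inv`.
#'
#' @inheritParams eig_direct
#' @param H_inv optional precomputed inverse of `H`.
#' @return Scalar EIG, equal to the direct form up to round-off.
#' @export
eig_fast <- function(H, G_list, sigma_y, n_y = NULL, H_inv = NULL) {
  if (length(G_list) == 0) return(0)
  A_inv <- if (is.null(H_inv)) chol2inv(chol(symmetrize(H))) else H_inv
  total <- 0
  n <- length(G_list)
  for (i in seq_len(n)) {
    G <- G_list[[i]]
    ny <- block_size(sigma_y, n_y, nrow(G))
    S <- expand_sigma(sigma_y, nrow(G))
    M <- G %*% A_inv %*% t(G)           # r_i x r_i, small
    total <- total + logdet_spd(S + M) - logdet_spd(S)
    if (i < n) A_inv <- woodbury_update(A_inv, G, sigma_y, n_y = ny)
  }
  total
}

#' Woodbury rank-update of an inverse precision matrix
#'
#' Given `A^-1`, returns `(A + G' Sigma_y^-1 G)^-1` using the Woodbury
#' matrix identity, so only a system of size `nrow(G)` is solved instead
#' of refactorizing the full matrix.
#'
#' @param A_inv current inverse (symmetric positive definite).
#' @param G sensitivity matrix of the added condition.
#' @inheritParams eig_direct
#' @return Updated inverse matrix of the same dimension as `A_inv`.
#' @export
woodbury_update <- function(A_inv, G, sigma_y, n_y = NULL) {
  if (nrow(G) == 0 || all(G == 0)) return(A_inv)
  ny <- block_size(sigma_y, n_y, nrow(G))
  S <- expand_sigma(sigma_y, nrow(G))
  AG <- A_inv %*% t(G)                  # n_theta x r
  inner <- symmetrize(S + G %*% AG)     # r x r
  symmetrize(A_inv - AG %*% solve_spd(inner, t(AG)))
}

#' Log-determinant of the Fisher information matrix
#'
#' `ln det(sum_i G_i' Sigma_y^-1 G_i)` — the classical D-optimality
#' criterion, provided for comparison with the Bayesian EIG. When the
#' summed information matrix is rank deficient (for example fewer total
#' output rows than parameters) the determinant is zero and `-Inf` is
#' returned as a documented sentinel rather than an error.
#'
#' @inheritParams eig_direct
#' @return Scalar log-determinant, or `-Inf` if rank deficient.
#' @export
fim_logdet <- function(G_list, sigma_y, n_y = NULL) {
  if (length(G_list) == 0) return(-Inf)
  n_theta <- ncol(G_list[[1]])
  FIM <- matrix(0, n_theta, n_theta)
  for (G in G_list) {
    ny <- block_size(sigma_y, n_y, nrow(G))
    FIM <- FIM + crossprod(G, prec_times(G, sigma_y, ny))
  }
  ev <- eigen(symmetrize(FIM), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * .Machine$double.eps * n_theta || min(ev) <= 0) {
    return(-Inf)
  }
  sum(log(ev))
}

#' Combined profit + information acquisition score
#'
#' `profit + w_I * eig`: the exploitation term plus the exploration term
#' weighted by the exploration weight.
#'
#' @param profit predicted profit of the design.
#' @param eig expected information gain of the design.
#' @param w_I non-negative exploration weight.
#' @return Scalar acquisition value.
#' @export
acquisition_score <- function(profit, eig, w_I) {
  stopifnot(is.finite(profit), is.finite(eig), is.finite(w_I), w_I >= 0)
  profit + w_I * eig
}

#' Acquisition configuration
#'
#' @param batch_size number of conditions per selected design (>= 1).
#' @param w_I_init initial exploration weight for the escalation schedule.
#' @param w_I_factor multiplicative escalation step (> 1) applied whenever
#'   the acquisition maximiser is a condition already in the batch.
#' @param max_escalations safety cap on escalations per pick.
#' @return List of class `mirnn_acq_config`.
#' @export
acquisition_config <- function(batch_size = 5L, w_I_init = 1e-4,
                               w_I_factor = 10, max_escalations = 60L) {
  stopifnot(batch_size >= 1, w_I_init >= 0, w_I_factor > 1)
  structure(list(batch_size = as.integer(batch_size),
                 w_I_init = w_I_init, w_I_factor = w_I_factor,
                 max_escalations = as.integer(max_escalations)),
            class = "mirnn_acq_config")
}

# Sensitivities of every candidate condition at the MAP estimate.
candidate_sensitivities <- function(posterior, conditions) {
  lapply(conditions, function(cond) {
    posterior$model$jacobian(posterior$theta_map, cond)$G
  })
}

# Incremental EIG of each candidate given the running inverse precision.
incremental_eigs <- function(A_inv, G_list, sigma_y) {
  vapply(G_list, function(G) {
    S <- expand_sigma(sigma_y, nrow(G))
    logdet_spd(S + G %*% A_inv %*% t(G)) - logdet_spd(S)
  }, numeric(1))
}

#' Greedy batch design selection
#'
#' Implements the escalating-exploration greedy search: the first pick is
#' the candidate with maximal predicted profit; every subsequent pick
#' maximises `profit + w_I * incremental EIG`, where the incremental EIG
#' of a candidate is its information gain given the conditions already in
#' the batch (maintained with [woodbury_update()]). Whenever the
#' maximiser is already in the batch, `w_I` is multiplied by
#' `w_I_factor` and the pick repeated until a novel condition wins. Ties
#' are broken by lowest candidate index, so reruns are deterministic.
#'
#' @param posterior a `mirnn_posterior`.
#' @param conditions list of candidate conditions (the design space Q).
#' @param profits numeric vector of predicted profits per candidate (see
#'   [predicted_profits()]).
#' @param config an [acquisition_config()].
#' @param mode `"explore_exploit"` (full acquisition), `"explore"`
#'   (incremental EIG only, profit zeroed) or `"exploit"` (profit only
#'   with within-batch duplicate exclusion).
#' @param G_list optional precomputed candidate sensitivities.
#' @return List with `selected` (candidate indices in pick order),
#'   `eig_increment` and `w_I_at_selection` per pick, and `joint_eig` of
#'   the batch.
#' @export
greedy_select <- function(posterior, conditions, profits, config,
                          mode = c("explore_exploit", "explore",
                                   "exploit"),
                          G_list = NULL) {
  mode <- match.arg(mode)
  n_cand <- length(conditions)
  if (config$batch_size > n_cand) {
    stop("batch_size exceeds the number of candidate conditions")
  }
  sigma_y <- posterior$sigma_y
  need_eig <- mode != "exploit"
  if (need_eig && is.null(G_list)) {
    G_list <- candidate_sensitivities(posterior, conditions)
  }
  A_inv <- if (need_eig) chol2inv(chol(symmetrize(posterior$hessian)))
           else NULL
  selected <- integer(0)
  eig_inc <- numeric(0)
  w_trace <- numeric(0)
  w_I <- config$w_I_init
  for (pick in seq_len(config$batch_size)) {
    if (need_eig) {
      deig <- incremental_eigs(A_inv, G_list, sigma_y)
    } else {
      deig <- rep(0, n_cand)
    }
    if (mode == "explore") {
      score <- deig
      best <- pick_best(score, exclude = selected)
    } else if (mode == "exploit") {
      score <- profits
      best <- pick_best(score, exclude = selected)
    } else if (pick == 1L) {
      best <- pick_best(profits, exclude = integer(0))
    } else {
      esc <- 0L
      repeat {
        score <- profits + w_I * deig
        best <- pick_best(score, exclude = integer(0))
        if (!(best %in% selected)) break
        w_I <- w_I * config$w_I_factor
        esc <- esc + 1L
        if (esc > config$max_escalations) {
          best <- pick_best(score, exclude = selected)
          break
        }
      }
    }
    selected <- c(selected, best)
    eig_inc <- c(eig_inc, if (need_eig) deig[best] else NA_real_)
    w_trace <- c(w_trace, w_I)
    if (need_eig && pick < config$batch_size) {
      A_inv <- woodbury_update(A_inv, G_list[[best]], sigma_y)
    }
  }
  joint <- if (need_eig) {
    eig_fast(posterior$hessian, G_list[selected], sigma_y)
  } else NA_real_
  list(selected = selected, eig_increment = eig_inc,
       w_I_at_selection = w_trace, joint_eig = joint)
}

pick_best <- function(score, exclude) {
  s <- score
  if (length(exclude)) s[exclude] <- -Inf
  which.max(s)  # which.max returns the lowest index on ties
}

#' Model-predicted profits for candidate conditions
#'
#' Rolls out the posterior-mean (inference-mode, rectified) prediction
#' for each candidate and applies a profit function to the predicted
#' trajectory.
#'
#' @param posterior a `mirnn_posterior` whose model is a [mirnn_model()].
#' @param conditions list of candidate conditions (scaled units).
#' @param profit_fn `function(pred_y, condition)` mapping the
#'   `n_tau x n_y` predicted output matrix (original units if a scaling
#'   is stored in the posterior) and the condition to a scalar profit.
#' @return Numeric vector of predicted profits.
#' @export
predicted_profits <- function(posterior, conditions, profit_fn) {
  dims <- posterior$model$dims
  params <- unflatten_params(posterior$theta_map, dims)
  vapply(conditions, function(cond) {
    y <- predict_trajectory(params, cond, mode = "inference",
                            constrained = posterior$model$constrained)$y
    if (!is.null(posterior$scaling)) {
      y <- unscale_outputs(y, posterior$scaling)
    }
    profit_fn(y, cond)
  }, numeric(1))
}

#' Select a design under a named strategy
#'
#' The four strategies benchmarked in the closed loop: `random` draws a
#' seeded uniform sample without replacement; `explore` greedily maximises
#' incremental EIG; `exploit` greedily maximises predicted profit with
#' duplicate exclusion; `explore_exploit` runs the full escalating
#' acquisition of [greedy_select()].
#'
#' @inheritParams greedy_select
#' @param strategy one of `"random"`, `"explore"`, `"exploit"`,
#'   `"explore_exploit"`.
#' @param seed seed for the random strategy.
#' @return As [greedy_select()] (for `random`, EIG fields are `NA`).
#' @export
select_design <- function(posterior, conditions, profits, config,
                          strategy = c("explore_exploit", "explore",
                                       "exploit", "random"),
                          seed = 1L, G_list = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "random") {
    if (config$batch_size > length(conditions)) {
      stop("batch_size exceeds the number of candidate conditions")
    }
    sel <- with_seed(seed,
                     sample.int(length(conditions), config$batch_size))
    return(list(selected = sel,
                eig_increment = rep(NA_real_, config$batch_size),
                w_I_at_selection = rep(NA_real_, config$batch_size),
                joint_eig = NA_real_))
  }
  greedy_select(posterior, conditions, profits, config, mode = strategy,
                G_list = G_list)
}
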