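#' @title Closed-loop design-test-learn optimization
#' @description
#' Sequential rounds of fit (MAP + Laplace), design (strategy-driven
#' batch selection), test (simulate the selected configurations on the
#' ground-truth bioreactor with measurement noise) and learn (append the
#' new data), tracking best-found profit and model accuracy over the
#' whole enumerated design space.
#' @name dtl
NULL

#' Pearson correlation and RMSE between predictions and truth
#'
#' @param pred,truth aligned numeric vectors.
#' @return List with `pearson_r` (NA if either vector has zero variance)
#'   and `rmse`.
#' @export
pearson_rmse <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  r <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0) NA_real_
       else stats::cor(pred, truth)
  list(pearson_r = r, rmse = sqrt(mean((pred - truth)^2)))
}

# Model-predicted end-point metabolite concentration per configuration
# (rectified rollout at theta_MAP, unscaled); multiplied by the
# feed-implied final volume when `final_volumes` is given, yielding
# predicted product mass for the profit term.
endpoint_predictions <- function(posterior, conditions_raw,
                                 final_volumes = NULL) {
  dims <- posterior$model$dims
  params <- unflatten_params(posterior$theta_map, dims)
  vapply(seq_along(conditions_raw), function(i) {
    cond <- scale_condition(conditions_raw[[i]], posterior$scaling)
    y <- predict_trajectory(params, cond, mode = "inference",
                            constrained = posterior$model$constrained)$y
    y <- unscale_outputs(y, posterior$scaling)
    m_T <- y[nrow(y), dims$n_y]
    if (is.null(final_volumes)) m_T else m_T * final_volumes[i]
  }, numeric(1))
}

#' Noiseless ground-truth end points over a design space
#'
#' One simulation per configuration with noise off; the reference values
#' model accuracy is judged against. The evaluation quantity is the
#' end-point metabolite concentration (g/L); `"mass"` returns the
#' end-point product mass (the profit) instead.
#'
#' @param ecosystem a `bioreactor_params`.
#' @param space a `bioreactor_design_space`.
#' @param quantity `"concentration"` (default) or `"mass"`.
#' @inheritParams simulate_bioreactor
#' @return Numeric vector, one value per configuration.
#' @export
ground_truth_endpoints <- function(ecosystem, space,
                                   t_grid = seq(0, 130, by = 26),
                                   V0 = 1, s0 = 0.01, r0 = 0,
                                   rf_conc = 1,
                                   quantity = c("concentration",
                                                "mass")) {
  quantity <- match.arg(quantity)
  vapply(space$designs, function(d) {
    tr <- simulate_bioreactor(ecosystem, d, V0 = V0, s0 = s0, r0 = r0,
                              t_grid = t_grid, rf_conc = rf_conc,
                              noise_pct = 0)
    if (quantity == "mass") profit(tr) else tr$m[length(tr$times)]
  }, numeric(1))
}

#' Model accuracy over the full design space
#'
#' Compares model-predicted end-point metabolite concentrations against
#' noiseless ground-truth values for every configuration in the space.
#'
#' @param posterior a fitted `mirnn_posterior` (with scaling).
#' @param space a `bioreactor_design_space`.
#' @param truth_endpoints noiseless ground-truth end-point metabolite
#'   concentrations per configuration (see [ground_truth_endpoints()]).
#' @inheritParams simulate_bioreactor
#' @return List with `pearson_r` and `rmse`.
#' @export
evaluate_model <- function(posterior, space, truth_endpoints,
                           t_grid = seq(0, 130, by = 26), V0 = 1,
                           s0 = 0.01, rf_conc = 1) {
  n_s <- posterior$model$dims$n_s
  conds <- lapply(space$designs, design_to_condition, t_grid = t_grid,
                  s0 = s0, n_s = n_s, rf_conc = rf_conc)
  pred <- endpoint_predictions(posterior, conds)
  pearson_rmse(pred, truth_endpoints)
}

#' Run the closed design-test-learn loop
#'
#' Cycle 0 tests `n_init` seeded-random configurations. Each subsequent
#' cycle refits the posterior on all data so far (optionally re-estimating
#' the noise covariance by EM), records model accuracy over the whole
#' space and the best profit observed so far, selects `batch_size` new
#' configurations among those not yet tested using the given strategy,
#' simulates them with measurement noise, and appends the data. After
#' `n_cycles` cycles, `n_init + n_cycles * batch_size` configurations
#' have been tested.
#'
#' @param ecosystem a `bioreactor_params` ground truth.
#' @param space a `bioreactor_design_space`.
#' @param strategy `"explore_exploit"`, `"explore"`, `"exploit"` or
#'   `"random"`.
#' @param n_init configurations in the initial random design.
#' @param batch_size configurations selected per cycle.
#' @param n_cycles number of DTL cycles.
#' @param seed master seed; all randomness (initial design, measurement
#'   noise, random-strategy draws) derives from it.
#' @param n_h hidden size of the surrogate MiRNN.
#' @param alpha prior precision for the MAP fit.
#' @param sigma_y initial/fixed diagonal noise variance.
#' @param estimate_sigma re-estimate the noise covariance by EM each
#'   cycle.
#' @param n_em_iter EM iterations when `estimate_sigma` is `TRUE`.
#' @param truth_endpoints optional precomputed
#'   [ground_truth_endpoints()]; computed if missing and
#'   `eval_space = TRUE`.
#' @param eval_space record model accuracy over the whole space each
#'   cycle (requires the noiseless endpoints).
#' @param config an [acquisition_config()] (its `batch_size` is
#'   overridden by `batch_size`).
#' @param t_grid,V0,s0,r0,rf_conc,noise_pct simulator settings.
#' @param tol,max_iter MAP fit controls.
#' @return Object of class `mirnn_dtl_history`: `cycles` data.frame
#'   (cycle, n_tested, best_profit, pearson_r, rmse), `tested`
#'   (configuration indices in test order), `profits` (observed per
#'   tested configuration), `selections` (per-cycle pick details),
#'   `posterior` (final fit) and the run settings.
#' @export
run_dtl <- function(ecosystem, space,
                    strategy = c("explore_exploit", "explore", "exploit",
                                 "random"),
                    n_init = 5L, batch_size = 5L, n_cycles = 5L,
                    seed = 1L, n_h = 8L, alpha = 1, sigma_y = 1e-3,
                    estimate_sigma = TRUE, n_em_iter = 2L,
                    truth_endpoints = NULL, eval_space = TRUE,
                    config = acquisition_config(),
                    t_grid = seq(0, 130, by = 26), V0 = 1, s0 = 0.01,
                    r0 = 0, rf_conc = 1, noise_pct = 0.05,
                    tol = 1e-4, max_iter = 60L) {
  strategy <- match.arg(strategy)
  n_conf <- length(space$designs)
  if (n_init + n_cycles * batch_size > n_conf) {
    stop("design space too small for n_init + n_cycles * batch_size")
  }
  config$batch_size <- as.integer(batch_size)
  dims <- mirnn_dims(n_s = ecosystem$n_s, n_m = 1L,
                     n_u = 1L + ecosystem$n_r, n_h = n_h,
                     n_tau = length(t_grid) - 1L)
  conds_raw <- lapply(seq_len(n_conf), function(i) {
    design_to_condition(space$designs[[i]], t_grid = t_grid, s0 = s0,
                        n_s = ecosystem$n_s, rf_conc = rf_conc,
                        id = sprintf("config_%04d", i))
  })
  vols <- vapply(space$designs, design_final_volume,
                 t_span = range(t_grid), V0 = V0, numeric(1))
  if (eval_space && is.null(truth_endpoints)) {
    truth_endpoints <- ground_truth_endpoints(ecosystem, space,
                                              t_grid = t_grid, V0 = V0,
                                              s0 = s0, r0 = r0,
                                              rf_conc = rf_conc)
  }
  seeds <- derive_seeds(seed, 1L + n_conf + n_cycles)
  noise_seed <- function(i) seeds[1L + i]
  cycle_seed <- function(l) seeds[1L + n_conf + l]

  run_config <- function(i) {
    traj <- simulate_bioreactor(ecosystem, space$designs[[i]], V0 = V0,
                                s0 = s0, r0 = r0, t_grid = t_grid,
                                rf_conc = rf_conc,
                                noise_pct = noise_pct,
                                seed = noise_seed(i))
    list(obs = trajectory_observations(traj, TRUE),
         profit = profit(traj, observed = noise_pct > 0))
  }

  tested <- with_seed(seeds[1], sample.int(n_conf, n_init))
  runs <- lapply(tested, run_config)
  observations <- lapply(runs, `[[`, "obs")
  profits_obs <- vapply(runs, `[[`, numeric(1), "profit")

  cycles <- data.frame(cycle = integer(0), n_tested = integer(0),
                       best_profit = numeric(0), pearson_r = numeric(0),
                       rmse = numeric(0))
  selections <- list()
  theta_warm <- NULL
  posterior <- NULL
  sigma_cur <- sigma_y

  for (l in seq_len(n_cycles) - 1L) {
    raw_ds <- mirnn_dataset(conds_raw[tested], observations, dims)
    scaling <- fit_scaling(raw_ds)
    ds <- scale_dataset(raw_ds, scaling)
    model <- mirnn_model(dims)
    if (is.null(theta_warm)) {
      theta_warm <- training_init(dims, ds, seed = seeds[1])
    }
    if (estimate_sigma) {
      em <- estimate_sigma_y_em(model, ds, alpha,
                                sigma_y_init = sigma_cur,
                                n_em_iter = n_em_iter,
                                init = theta_warm, max_iter = max_iter)
      sigma_cur <- em$sigma_y
      posterior <- structure(
        list(theta_map = em$theta_map, hessian = em$hessian,
             alpha = alpha, sigma_y = sigma_cur, scaling = scaling,
             model = model, fit = em$fit),
        class = "mirnn_posterior")
    } else {
      posterior <- fit_posterior(model, ds, alpha, sigma_cur,
                                 init = theta_warm, tol = tol,
                                 max_iter = max_iter, scaling = scaling,
                                 quiet = TRUE)
    }
    theta_warm <- posterior$theta_map

    metrics <- if (eval_space) {
      pred <- endpoint_predictions(posterior, conds_raw)
      pearson_rmse(pred, truth_endpoints)
    } else list(pearson_r = NA_real_, rmse = NA_real_)
    cycles <- rbind(cycles, data.frame(
      cycle = l, n_tested = length(tested),
      best_profit = max(profits_obs),
      pearson_r = metrics$pearson_r, rmse = metrics$rmse))

    candidates <- setdiff(seq_len(n_conf), tested)
    cand_conds <- lapply(conds_raw[candidates], scale_condition, scaling)
    cand_profits <- endpoint_predictions(posterior, conds_raw[candidates],
                                         vols[candidates])
    sel <- select_design(posterior, cand_conds, cand_profits, config,
                         strategy = strategy, seed = cycle_seed(l + 1L))
    picked <- candidates[sel$selected]
    new_runs <- lapply(picked, run_config)
    tested <- c(tested, picked)
    observations <- c(observations, lapply(new_runs, `[[`, "obs"))
    profits_obs <- c(profits_obs,
                     vapply(new_runs, `[[`, numeric(1), "profit"))
    selections[[l + 1L]] <- list(cycle = l + 1L, config_ids = picked,
                                 profit_pred = cand_profits[sel$selected],
                                 eig_increment = sel$eig_increment,
                                 w_I_at_selection = sel$w_I_at_selection,
                                 joint_eig = sel$joint_eig)
  }

  # final learn phase: refit on all data and record closing metrics
  raw_ds <- mirnn_dataset(conds_raw[tested], observations, dims)
  scaling <- fit_scaling(raw_ds)
  ds <- scale_dataset(raw_ds, scaling)
  model <- mirnn_model(dims)
  posterior <- fit_posterior(model, ds, alpha, sigma_cur,
                             init = theta_warm, tol = tol,
                             max_iter = max_iter, scaling = scaling,
                             quiet = TRUE)
  metrics <- if (eval_space) {
    pred <- endpoint_predictions(posterior, conds_raw)
    pearson_rmse(pred, truth_endpoints)
  } else list(pearson_r = NA_real_, rmse = NA_real_)
  cycles <- rbind(cycles, data.frame(
    cycle = n_cycles, n_tested = length(tested),
    best_profit = max(profits_obs),
    pearson_r = metrics$pearson_r, rmse = metrics$rmse))

  structure(list(cycles = cycles, tested = tested,
                 profits = profits_obs, selections = selections,
                 posterior = posterior, strategy = strategy,
                 seed = seed,
                 settings = list(n_init = n_init,
                                 batch_size = batch_size,
                                 n_cycles = n_cycles, n_h = n_h,
                                 alpha = alpha, noise_pct = noise_pct)),
            class = "mirnn_dtl_history")
}

#' Selected-design table of a DTL run
#'
#' One row per selected condition across all cycles: candidate
#' configuration id, its resource bitmask and feed-profile index, the
#' rank within its batch, the model-predicted profit, the incremental
#' EIG at selection and the exploration weight in force.
#'
#' @param history a `mirnn_dtl_history` from [run_dtl()].
#' @param space the `bioreactor_design_space` the run used.
#' @return data.frame, empty if no cycles were run.
#' @export
design_table <- function(history, space) {
  rows <- lapply(history$selections, function(sel) {
    meta <- space$meta[sel$config_ids, ]
    data.frame(cycle = sel$cycle,
               candidate_id = sel$config_ids,
               resource_bitmask = meta$resource_bitmask,
               feed_profile_id = meta$feed_profile_id,
               rank = seq_along(sel$config_ids),
               profit_pred = sel$profit_pred,
               eig_increment = sel$eig_increment,
               w_I_at_selection = sel$w_I_at_selection)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cycle = integer(0), candidate_id = integer(0),
                      resource_bitmask = integer(0),
                      feed_profile_id = integer(0), rank = integer(0),
                      profit_pred = numeric(0),
                      eig_increment = numeric(0),
                      w_I_at_selection = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.mirnn_dtl_history <- function(x, ...) {
  cat(sprintf("DTL run (%s): %d configurations tested over %d cycles\n",
              x$strategy, length(x$tested), x$settings$n_cycles))
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' Repeated k-fold cross-validation of trajectory prediction
#'
#' Randomly partitions the conditions (communities) of a dataset into
#' `k_folds` test sets per trial, fits on the remaining conditions
#' (scaling refit on each training split), predicts the held-out
#' conditions autoregressively from their initial states, and scores
#' per-species Pearson correlation and RMSE pooled over held-out
#' conditions and time points. Only species initially present in a
#' condition enter the evaluation, so the constraint cannot trivially
#' inflate the constrained model's score on absent species.
#'
#' @param dataset a [mirnn_dataset()] in original units.
#' @param k_folds number of folds (at most the number of conditions).
#' @param n_trials repetitions with reshuffled partitions.
#' @param model_variant `"constrained"` (absent-species mask active) or
#'   `"unconstrained"` (the ablation).
#' @param seed master seed for the partitions.
#' @param n_h hidden size of the fitted model.
#' @param alpha prior precision.
#' @param sigma_y diagonal noise variance used in the fit.
#' @param tol,max_iter MAP fit controls.
#' @return List of class `mirnn_cv`: `trials` data.frame (trial, median
#'   and IQR of per-species Pearson R and RMSE), `species` data.frame of
#'   per-trial per-species metrics, and the settings.
#' @export
crossvalidate <- function(dataset, k_folds = 10L, n_trials = 5L,
                          model_variant = c("constrained",
                                            "unconstrained"),
                          seed = 0L, n_h = 16L, alpha = 1,
                          sigma_y = 1e-3, tol = 1e-4, max_iter = 60L) {
  model_variant <- match.arg(model_variant)
  n_cond <- length(dataset)
  if (k_folds > n_cond) stop("more folds than conditions")
  d0 <- dataset$dims
  dims <- mirnn_dims(d0$n_s, d0$n_m, d0$n_u, n_h, d0$n_tau)
  model <- mirnn_model(dims, constrained = model_variant == "constrained")
  trial_seeds <- derive_seeds(seed, n_trials)

  species_rows <- list()
  trial_rows <- list()
  for (trial in seq_len(n_trials)) {
    fold_of <- with_seed(trial_seeds[trial], {
      rep_len(seq_len(k_folds), n_cond)[sample.int(n_cond)]
    })
    pred_pool <- vector("list", d0$n_s)
    obs_pool <- vector("list", d0$n_s)
    theta_warm <- NULL
    for (fold in seq_len(k_folds)) {
      test_idx <- which(fold_of == fold)
      train_idx <- setdiff(seq_len(n_cond), test_idx)
      if (length(test_idx) == 0) stop("fold with no test conditions")
      train_raw <- subset_dataset(dataset, train_idx)
      scaling <- fit_scaling(train_raw)
      train_ds <- scale_dataset(train_raw, scaling)
      if (is.null(theta_warm)) {
        theta_warm <- training_init(dims, train_ds,
                                    seed = trial_seeds[trial])
      }
      fit <- fit_map(model, train_ds, alpha, sigma_y,
                     init = theta_warm, tol = tol, max_iter = max_iter,
                     quiet = TRUE)
      theta_warm <- fit$theta
      params <- unflatten_params(fit$theta, dims)
      for (i in test_idx) {
        cond <- scale_condition(dataset$conditions[[i]], scaling)
        y <- predict_trajectory(params, cond, mode = "inference",
                                constrained = model$constrained)$y
        y <- unscale_outputs(y, scaling)
        obs <- dataset$observations[[i]]
        present <- which(dataset$conditions[[i]]$s0 > 0)
        for (sp in present) {
          pred_pool[[sp]] <- c(pred_pool[[sp]], y[, sp])
          obs_pool[[sp]] <- c(obs_pool[[sp]], obs[, sp])
        }
      }
    }
    per_species <- do.call(rbind, lapply(seq_len(d0$n_s), function(sp) {
      if (length(pred_pool[[sp]]) < 3) {
        return(data.frame(trial = trial, species = sp,
                          pearson_r = NA_real_, rmse = NA_real_,
                          n_points = length(pred_pool[[sp]])))
      }
      m <- pearson_rmse(pred_pool[[sp]], obs_pool[[sp]])
      data.frame(trial = trial, species = sp, pearson_r = m$pearson_r,
                 rmse = m$rmse, n_points = length(pred_pool[[sp]]))
    }))
    species_rows[[trial]] <- per_species
    r <- per_species$pearson_r
    e <- per_species$rmse
    trial_rows[[trial]] <- data.frame(
      trial = trial,
      median_r = stats::median(r, na.rm = TRUE),
      iqr_r = stats::IQR(r, na.rm = TRUE),
      median_rmse = stats::median(e, na.rm = TRUE),
      iqr_rmse = stats::IQR(e, na.rm = TRUE))
  }
  structure(list(trials = do.call(rbind, trial_rows),
                 species = do.call(rbind, species_rows),
                 settings = list(k_folds = k_folds, n_trials = n_trials,
                                 model_variant = model_variant,
                                 n_h = n_h, alpha = alpha,
                                 sigma_y = sigma_y, seed = seed)),
            class = "mirnn_cv")
}

#' @export
print.mirnn_cv <- function(x, ...) {
  cat(sprintf("%s MiRNN %d-fold CV over %d trials\n",
              x$settings$model_variant, x$settings$k_folds,
              x$settings$n_trials))
  print(x$trials, row.names = FALSE)
  invisible(x)
}
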