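# MAP objective, Newton fit, Laplace Hessian, predictive distribution,
# noise-covariance EM, evidence and held-out likelihood.

empty_dataset <- function() list(conditions = list(), observations = list())

test_that("MAP objective vanishes at the prior mode and is evaluated directly", {
  m <- linear_model(4, 2)
  expect_identical(neg_log_posterior(rep(0, 4), m, empty_dataset(),
                                     alpha = 2, sigma_y = 1), 0)
  ds <- linear_dataset(4, 2, 1, theta_true = rep(0, 4), sigma = 0.5,
                       seed = 3)
  theta <- rep(0, 4)
  # direct evaluation oracle: residuals are the observations themselves
  r <- ds$observations[[1]]
  expect_equal(neg_log_posterior(theta, m, ds, alpha = 2, sigma_y = 0.5),
               0.5 * sum(r^2 / 0.5))
  # doubling alpha doubles the prior penalty only
  theta2 <- rep(0.3, 4)
  f1 <- neg_log_posterior(theta2, m, ds, alpha = 1, sigma_y = 0.5)
  f2 <- neg_log_posterior(theta2, m, ds, alpha = 2, sigma_y = 0.5)
  expect_equal(f2 - f1, 0.5 * sum(theta2^2))
})

test_that("MAP fit reproduces the closed-form ridge solution on linear models", {
  n_theta <- 6; n_y <- 3
  m <- linear_model(n_theta, n_y)
  set.seed(10)
  theta_true <- rnorm(n_theta)
  ds <- linear_dataset(n_theta, n_y, 5, theta_true, sigma = 0.2,
                       seed = 20)
  fit <- fit_map(m, ds, alpha = 0.5, sigma_y = 0.2, tol = 1e-10)
  ref <- ridge_posterior(ds, 0.5, 0.2, n_theta, n_y)
  expect_true(fit$converged)
  expect_equal(fit$theta, ref$mean, tolerance = 1e-8)
  expect_lte(fit$grad_norm, 1e-10)
  # empty dataset returns the prior mode
  fit0 <- fit_map(m, empty_dataset(), alpha = 1, sigma_y = 1)
  expect_identical(fit0$theta, rep(0, n_theta))
})

test_that("non-convergence is flagged, not silent", {
  m <- linear_model(3, 2)
  ds <- linear_dataset(3, 2, 4, rnorm(3), sigma = 0.1, seed = 5)
  expect_warning(fit <- fit_map(m, ds, alpha = 1, sigma_y = 0.1,
                                max_iter = 0L),
                 "did not converge")
  expect_false(fit$converged)
})

test_that("Laplace Hessian is the prior precision plus summed information", {
  n_theta <- 5; n_y <- 2
  m <- linear_model(n_theta, n_y)
  ds <- linear_dataset(n_theta, n_y, 1, rnorm(n_theta), sigma = 0.3,
                       seed = 7)
  H0 <- laplace_hessian(m, rep(0, n_theta), empty_dataset(), alpha = 2,
                        sigma_y = 0.3)
  expect_equal(H0, diag(2, n_theta))
  H1 <- laplace_hessian(m, rep(0, n_theta), ds, alpha = 2, sigma_y = 0.3)
  G <- ds$conditions[[1]]$G
  expect_equal(H1 - H0, t(G) %*% G / 0.3, tolerance = 1e-12)
  # minimum eigenvalue bounded below by the prior precision
  ev <- eigen(H1, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 2 - 1e-9)
})

test_that("posterior predictive matches the exact linear-Gaussian posterior", {
  n_theta <- 6; n_y <- 3
  m <- linear_model(n_theta, n_y)
  theta_true <- rnorm(n_theta)
  ds <- linear_dataset(n_theta, n_y, 6, theta_true, sigma = 0.2,
                       seed = 31)
  post <- fit_posterior(m, ds, alpha = 0.7, sigma_y = 0.2, tol = 1e-10)
  new_cond <- list(G = matrix(rnorm(n_y * n_theta), n_y, n_theta))
  pp <- posterior_predictive(post, new_cond)
  ref <- ridge_posterior(ds, 0.7, 0.2, n_theta, n_y)
  expect_equal(pp$mean, as.numeric(new_cond$G %*% ref$mean),
               tolerance = 1e-8)
  ref_cov <- diag(0.2, n_y) +
    new_cond$G %*% solve(ref$precision, t(new_cond$G))
  expect_equal(pp$cov, (ref_cov + t(ref_cov)) / 2, tolerance = 1e-8)
  # epistemic part is positive semidefinite
  ev <- eigen(pp$cov - pp$cov_aleatory, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # overwhelming prior drives the covariance to the noise floor
  post_tight <- fit_posterior(m, ds, alpha = 1e12, sigma_y = 0.2,
                              tol = 1e-8)
  pp_tight <- posterior_predictive(post_tight, new_cond)
  expect_equal(pp_tight$cov, pp_tight$cov_aleatory, tolerance = 1e-8)
})

test_that("adding data never increases linearized predictive variance", {
  n_theta <- 5; n_y <- 2
  m <- linear_model(n_theta, n_y)
  ds <- linear_dataset(n_theta, n_y, 6, rnorm(n_theta), sigma = 0.3,
                       seed = 13)
  probe <- list(G = matrix(rnorm(n_y * n_theta), n_y, n_theta))
  vars <- sapply(2:6, function(k) {
    sub <- list(conditions = ds$conditions[1:k],
                observations = ds$observations[1:k])
    post <- fit_posterior(m, sub, alpha = 1, sigma_y = 0.3, tol = 1e-9,
                          quiet = TRUE)
    diag(posterior_predictive(post, probe)$cov)
  })
  for (k in 2:ncol(vars)) expect_true(all(vars[, k] <= vars[, k - 1] + 1e-10))
})

test_that("analytic rollout sensitivities agree with central finite differences", {
  d <- tiny_dims()
  p <- init_params(d, seed = 21, scale = 0.4)
  cond <- seeded_condition(d, seed = 22)
  theta <- flatten_params(p)
  for (constrained in c(TRUE, FALSE)) {
    a <- mirnn_sensitivity(theta, cond, d, constrained = constrained)
    b <- mirnn_sensitivity_fd(theta, cond, d, constrained = constrained)
    expect_equal(a$pred, b$pred, tolerance = 1e-9)
    denom <- max(abs(b$G))
    expect_lt(max(abs(a$G - b$G)) / denom, 1e-4)
  }
  # rows of species absent at t = 0 carry exactly zero sensitivity
  cond0 <- seeded_condition(d, seed = 22, s0 = c(0, 0.5))
  s0_rows <- seq(1, d$n_tau * d$n_y, by = d$n_y)
  expect_true(all(mirnn_sensitivity(theta, cond0, d)$G[s0_rows, ] == 0))
})

test_that("noise-covariance EM recovers known noise and floors perfect fits", {
  n_theta <- 4; n_y <- 2
  m <- linear_model(n_theta, n_y)
  theta_true <- c(0.5, -0.3, 0.8, 0.1)
  sigma_true <- 0.04
  ds <- linear_dataset(n_theta, n_y, 120, theta_true, sigma = sigma_true,
                       seed = 41)
  em <- estimate_sigma_y_em(m, ds, alpha = 1e-6, sigma_y_init = 1,
                            n_em_iter = 8)
  expect_true(all(abs(em$sigma_y - sigma_true) / sigma_true < 0.2))
  # zero-residual data collapse to the configured floor
  ds_perfect <- ds
  ds_perfect$observations <- lapply(ds$conditions, function(cond) {
    as.numeric(cond$G %*% theta_true)
  })
  em0 <- estimate_sigma_y_em(m, ds_perfect, alpha = 1e-8,
                             sigma_y_init = 1, n_em_iter = 8,
                             floor = 1e-8)
  expect_true(all(em0$sigma_y < 1e-4))
  expect_true(all(em0$sigma_y >= 1e-8))
})

test_that("held-out log-likelihood has the Gaussian closed forms", {
  mk <- function(mean, cov) {
    structure(list(mean = mean, cov = cov, cov_aleatory = cov),
              class = "mirnn_predictive")
  }
  # observation at the mean with identity covariance in two dimensions
  p <- mk(c(0, 0), diag(2))
  expect_equal(heldout_loglik(list(p), list(c(0, 0))), -log(2 * pi))
  # inflating the covariance helps a far-off observation
  far <- c(5, -5)
  ll_small <- heldout_loglik(list(mk(c(0, 0), diag(2))), list(far))
  ll_big <- heldout_loglik(list(mk(c(0, 0), 20 * diag(2))), list(far))
  expect_gt(ll_big, ll_small)
  # batch score is the sum of per-item scores
  preds <- list(mk(c(0, 0), diag(2)), mk(c(1, 1), 2 * diag(2)))
  obs <- list(c(0.3, -0.2), c(1.4, 0.6))
  expect_equal(heldout_loglik(preds, obs),
               heldout_loglik(preds[1], obs[1]) +
                 heldout_loglik(preds[2], obs[2]))
})

test_that("Laplace evidence equals the exact linear-Gaussian marginal likelihood", {
  n_theta <- 5; n_y <- 2
  m <- linear_model(n_theta, n_y)
  ds <- linear_dataset(n_theta, n_y, 7, rnorm(n_theta), sigma = 0.3,
                       seed = 55)
  for (alpha in c(0.2, 1, 5)) {
    fit <- fit_map(m, ds, alpha, sigma_y = 0.3, tol = 1e-10)
    ev <- log_evidence(m, ds, alpha, 0.3, fit$theta)
    expect_equal(ev, linear_log_marginal(ds, alpha, 0.3, n_theta, n_y),
                 tolerance = 1e-7)
  }
})

test_that("evidence maximisation honours its grid contract", {
  n_theta <- 4; n_y <- 2
  m <- linear_model(n_theta, n_y)
  ds <- linear_dataset(n_theta, n_y, 10, rnorm(n_theta, sd = 2),
                       sigma = 0.1, seed = 66)
  expect_error(optimize_alpha(m, ds, 0.1, alpha_grid = numeric(0)),
               "empty")
  one <- optimize_alpha(m, ds, 0.1, alpha_grid = 3.7)
  expect_identical(one$alpha, 3.7)
  sel <- optimize_alpha(m, ds, 0.1, alpha_grid = 10^seq(-3, 2))
  expect_identical(unname(sel$alpha),
                   unname(10^seq(-3, 2)[which.max(sel$evidence)]))
})
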