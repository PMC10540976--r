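# EIG machinery, Woodbury updates, acquisition and greedy batch search.

random_G_list <- function(n, n_y, n_theta, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(rnorm(n_y * n_theta), n_y,
                                        n_theta))
}

test_that("direct EIG has its closed forms", {
  H <- random_spd(6, seed = 1)
  expect_identical(eig_direct(H, list(), 1), 0)
  # scalar case: H = 1, G = 1, sigma = 1 gives ln 2
  expect_equal(eig_direct(matrix(1), list(matrix(1)), 1), log(2))
})

test_that("fast EIG equals direct EIG and the single-condition identity", {
  for (n_theta in c(5, 50, 200)) {
    for (n in c(1, 5, 10)) {
      n_y <- 3
      H <- random_spd(n_theta, seed = n_theta + n)
      Gl <- random_G_list(n, n_y, n_theta, seed = n_theta * n)
      sy <- runif(n_y, 0.5, 2)
      e_direct <- eig_direct(H, Gl, sy)
      e_fast <- eig_fast(H, Gl, sy)
      expect_lt(abs(e_fast - e_direct) / max(abs(e_direct), 1e-12), 1e-6)
      expect_gte(e_fast, -1e-10)  # EIG is non-negative
    }
  }
  # n = 1 equals ln det(I + Sigma^-1 G H^-1 G')
  H <- random_spd(20, seed = 3)
  G <- random_G_list(1, 4, 20, seed = 4)[[1]]
  sy <- runif(4, 0.5, 2)
  ident <- determinant(diag(4) + diag(1 / sy) %*% G %*% solve(H) %*% t(G),
                       logarithm = TRUE)$modulus[1]
  expect_equal(eig_fast(H, list(G), sy), ident, tolerance = 1e-8)
  # zero sensitivities add no information
  expect_equal(eig_fast(H, list(matrix(0, 4, 20)), sy), 0)
})

test_that("EIG accumulates monotonically and ignores condition order", {
  n_theta <- 30; n_y <- 3
  H <- random_spd(n_theta, seed = 9)
  Gl <- random_G_list(6, n_y, n_theta, seed = 10)
  sy <- runif(n_y, 0.5, 2)
  cum <- sapply(seq_along(Gl), function(k) eig_direct(H, Gl[1:k], sy))
  expect_true(all(diff(cum) > -1e-10))
  set.seed(11)
  perm <- sample(length(Gl))
  expect_equal(eig_fast(H, Gl[perm], sy), eig_direct(H, Gl, sy),
               tolerance = 1e-8)
})

test_that("Woodbury update equals dense re-inversion", {
  A <- random_spd(20, seed = 12)
  A_inv <- solve(A)
  G <- random_G_list(1, 3, 20, seed = 13)[[1]]
  sy <- runif(3, 0.5, 2)
  updated <- woodbury_update(A_inv, G, sy)
  dense <- solve(A + t(G) %*% diag(1 / sy) %*% G)
  expect_equal(updated, dense, tolerance = 1e-8)
  expect_identical(woodbury_update(A_inv, matrix(0, 3, 20), sy), A_inv)
  expect_equal(woodbury_update(matrix(1), matrix(1), 1), matrix(0.5))
})

test_that("Fisher-information log-determinant matches eigenvalue oracle", {
  expect_equal(fim_logdet(list(diag(4)), rep(1, 4)), 0)
  # fewer rows than parameters: rank deficient, sentinel not error
  G <- random_G_list(1, 2, 10, seed = 14)[[1]]
  expect_identical(fim_logdet(list(G), c(1, 1)), -Inf)
  Gl <- random_G_list(5, 3, 8, seed = 15)
  sy <- runif(3, 0.5, 2)
  FIM <- Reduce(`+`, lapply(Gl, function(G) t(G) %*% diag(1 / sy) %*% G))
  expect_equal(fim_logdet(Gl, sy),
               sum(log(eigen(FIM, symmetric = TRUE)$values)),
               tolerance = 1e-8)
})

test_that("acquisition score is profit plus weighted information", {
  expect_identical(acquisition_score(1.5, 3, 0), 1.5)
  expect_identical(acquisition_score(0, 0.7, 2), 1.4)
  expect_identical(acquisition_score(2, 0.5, 4), 4)
  expect_error(acquisition_config(w_I_factor = 1), "w_I_factor")
})

# A toy posterior over linear-surrogate candidate conditions.
toy_posterior <- function(n_theta, n_y, alpha = 1, sigma = 0.5,
                          seed = 1) {
  m <- linear_model(n_theta, n_y)
  structure(list(theta_map = rep(0, n_theta),
                 hessian = random_spd(n_theta, seed = seed,
                                      jitter = alpha),
                 alpha = alpha, sigma_y = sigma, scaling = NULL,
                 model = m, fit = list(converged = TRUE)),
            class = "mirnn_posterior")
}

test_that("greedy selection starts at max profit and fills small spaces", {
  post <- toy_posterior(8, 2)
  conds <- lapply(1:3, function(i) {
    list(G = random_G_list(1, 2, 8, seed = 20 + i)[[1]])
  })
  profits <- c(1, 3, 2)
  cfg <- acquisition_config(batch_size = 1)
  sel <- greedy_select(post, conds, profits, cfg)
  expect_identical(sel$selected, 2L)
  cfg3 <- acquisition_config(batch_size = 3)
  sel3 <- greedy_select(post, conds, profits, cfg3)
  expect_setequal(sel3$selected, 1:3)
  expect_error(greedy_select(post, conds, profits,
                             acquisition_config(batch_size = 4)),
               "batch_size")
})

test_that("greedy pair beats every other pair when profit dominates", {
  post <- toy_posterior(10, 2)
  n_cand <- 5
  conds <- lapply(seq_len(n_cand), function(i) {
    list(G = random_G_list(1, 2, 10, seed = 30 + i)[[1]])
  })
  set.seed(40)
  profits <- runif(n_cand)
  cfg <- acquisition_config(batch_size = 2, w_I_init = 1e-4)
  sel <- greedy_select(post, conds, profits, cfg)
  w_end <- sel$w_I_at_selection[2]
  joint_acq <- function(pair) {
    sum(profits[pair]) + w_end *
      eig_direct(post$hessian, lapply(conds[pair], `[[`, "G"),
                 post$sigma_y)
  }
  best <- joint_acq(sel$selected)
  pairs <- utils::combn(n_cand, 2)
  for (k in seq_len(ncol(pairs))) {
    expect_gte(best + 1e-9, joint_acq(pairs[, k]))
  }
})

test_that("exploration weight escalates until a novel condition wins", {
  post <- toy_posterior(6, 2)
  # candidate 1 has huge profit AND huge information: the profit pick and
  # the acquisition maximiser coincide, forcing escalation for pick 2
  conds <- list(list(G = 10 * diag(2) %x% t(rep(1, 3))),
                list(G = 5 * random_G_list(1, 2, 6, seed = 51)[[1]]),
                list(G = 5 * random_G_list(1, 2, 6, seed = 52)[[1]]))
  profits <- c(10, 0.1, 0.1)
  cfg <- acquisition_config(batch_size = 2, w_I_init = 1e-4,
                            w_I_factor = 10)
  sel <- greedy_select(post, conds, profits, cfg)
  expect_identical(sel$selected[1], 1L)
  expect_false(sel$selected[2] == 1L)
  expect_gt(sel$w_I_at_selection[2], cfg$w_I_init)
})

test_that("strategies are reproducible and respect their contracts", {
  post <- toy_posterior(8, 2)
  conds <- lapply(1:6, function(i) {
    list(G = random_G_list(1, 2, 8, seed = 60 + i)[[1]] * i)
  })
  set.seed(70)
  profits <- runif(6)
  cfg <- acquisition_config(batch_size = 3)
  r1 <- select_design(post, conds, profits, cfg, strategy = "random",
                      seed = 5)
  r2 <- select_design(post, conds, profits, cfg, strategy = "random",
                      seed = 5)
  expect_identical(r1$selected, r2$selected)
  expect_identical(anyDuplicated(r1$selected), 0L)
  # explore picks the max single-condition EIG first
  ex <- select_design(post, conds, profits, cfg, strategy = "explore")
  single <- sapply(conds, function(cc) {
    eig_fast(post$hessian, list(cc$G), post$sigma_y)
  })
  expect_identical(ex$selected[1], which.max(single))
  # exploit never repeats a condition within a batch
  xp <- select_design(post, conds, profits, cfg, strategy = "exploit")
  expect_identical(anyDuplicated(xp$selected), 0L)
  expect_identical(xp$selected[1], which.max(profits))
})
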