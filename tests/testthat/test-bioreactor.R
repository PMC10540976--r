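# Ground-truth ecosystem sampling, ODE integration, design enumeration,
# profit and the sparse-community dataset generator.

test_that("ecosystem sampling is reproducible and row-normalised", {
  e1 <- sample_ecosystem(5, 4, seed = 2)
  e2 <- sample_ecosystem(5, 4, seed = 2)
  expect_identical(e1$C, e2$C)
  expect_false(identical(e1$C, sample_ecosystem(5, 4, seed = 3)$C))
  expect_equal(rowSums(e1$Theta), rep(1, 5), tolerance = 1e-12)
  expect_true(all(e1$C >= 0))
  expect_equal(e1$d, rep(0.01, 4))
  expect_equal(e1$g, rep(0.01, 5))
  expect_equal(e1$k_d, 0.005)
  # exactly one producer, the species depending on fewest resources
  expect_identical(sum(e1$y_ms > 0), 1L)
  expect_identical(which(e1$y_ms > 0),
                   which.min(rowSums(e1$Theta > 0)))
  expect_equal(max(e1$y_ms), 0.5)
})

test_that("resource-dependence frequency matches its Bernoulli rate", {
  # one large draw: 10,000 species-resource pairs
  eco <- sample_ecosystem(500, 20, p_sr = 0.6, seed = 9)
  frac <- mean(eco$Theta > 0)
  expect_lt(abs(frac - 0.6), 0.02)
})

test_that("simulator reproduces analytic limits", {
  eco <- sample_ecosystem(5, 4, seed = 2)
  batch <- list(resource_mask = rep(1, 4), feed_profile = rep(0, 5))
  # product decay: no cells, no feed
  tr <- simulate_bioreactor(eco, batch, s0 = 0, m0 = 1, r0 = 0,
                            noise_pct = 0, rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$m, exp(-0.005 * tr$times), tolerance = 1e-6)
  # volume grows linearly under constant feed
  fed <- list(resource_mask = rep(1, 4), feed_profile = rep(0.01, 5))
  tr2 <- simulate_bioreactor(eco, fed, s0 = 0, noise_pct = 0,
                             rtol = 1e-10, atol = 1e-12)
  expect_equal(tr2$V, 1 + 0.01 * tr2$times, tolerance = 1e-8)
  # resources decay exponentially without consumers
  tr3 <- simulate_bioreactor(eco, batch, s0 = 0, r0 = 1, noise_pct = 0,
                             rtol = 1e-10, atol = 1e-12)
  for (j in 1:4) {
    expect_equal(tr3$r[, j], exp(-0.01 * tr3$times), tolerance = 1e-6)
  }
})

test_that("batch operation conserves volume and keeps states non-negative", {
  eco <- sample_ecosystem(6, 5, seed = 4)
  batch <- list(resource_mask = rep(1, 5), feed_profile = rep(0, 5))
  tr <- simulate_bioreactor(eco, batch, s0 = 0.05, r0 = 2,
                            noise_pct = 0)
  expect_equal(tr$V, rep(1, length(tr$times)), tolerance = 1e-10)
  expect_true(all(tr$r >= 0) && all(tr$s >= 0) && all(tr$m >= 0))
})

test_that("product only appears through producing species", {
  eco <- sample_ecosystem(4, 3, seed = 8)
  eco$y_ms <- rep(0, 4)  # no producer: product can only decay/dilute
  fed <- list(resource_mask = rep(1, 3), feed_profile = rep(0.01, 5))
  tr <- simulate_bioreactor(eco, fed, s0 = 0.05, m0 = 0.5, r0 = 1,
                            noise_pct = 0)
  expect_true(all(diff(tr$m) < 0))
  # dilution conserves product mass up to first-order decay
  mass <- tr$m * tr$V
  bound <- mass[1] * exp(-eco$k_d * (tr$times - tr$times[1]))
  expect_true(all(mass <= bound * (1 + 1e-6)))
})

test_that("measurement noise is multiplicative, clipped and seeded", {
  eco <- sample_ecosystem(5, 4, seed = 2)
  fed <- list(resource_mask = rep(1, 4), feed_profile = rep(0.02, 5))
  t1 <- simulate_bioreactor(eco, fed, seed = 3)
  t2 <- simulate_bioreactor(eco, fed, seed = 3)
  t3 <- simulate_bioreactor(eco, fed, seed = 4)
  expect_identical(t1$s_obs, t2$s_obs)
  expect_false(identical(t1$s_obs, t3$s_obs))
  expect_true(all(t1$s_obs >= 0))
  # relative perturbations have roughly the configured 5% spread
  rel <- (t1$s_obs[-1, ] - t1$s[-1, ]) / t1$s[-1, ]
  expect_lt(max(abs(rel)), 0.25)
  expect_gt(stats::sd(rel), 0.01)
})

test_that("design space enumeration has exact combinatorics and ordering", {
  catalog <- feed_profile_catalog(4, rates = c(0, 0.01), n_intervals = 3,
                                  seed = 1)
  sp <- enumerate_design_space(3, catalog)
  expect_identical(length(sp$designs), 7L * 4L)
  expect_identical(nrow(sp$meta), 28L)
  expect_identical(sp$meta$config_id, 1:28)
  # bitmask-major ordering, profile index minor
  expect_identical(sp$meta$resource_bitmask[1:4], rep(1L, 4))
  expect_identical(sp$meta$feed_profile_id[1:4], 1:4)
  one <- enumerate_design_space(1, matrix(0.01, 1, 5))
  expect_identical(length(one$designs), 1L)
})

test_that("feed profile catalog is distinct, non-zero and seeded", {
  cat1 <- feed_profile_catalog(20)
  expect_identical(dim(cat1), c(20L, 5L))
  expect_identical(anyDuplicated(cat1), 0L)
  expect_true(all(rowSums(cat1 != 0) > 0))
  expect_identical(cat1, feed_profile_catalog(20))
  expect_error(feed_profile_catalog(1000), "fewer distinct")
})

test_that("profit is end-point product mass", {
  eco <- sample_ecosystem(5, 4, seed = 2)
  fed <- list(resource_mask = rep(1, 4), feed_profile = rep(0.02, 5))
  tr <- simulate_bioreactor(eco, fed, noise_pct = 0)
  n <- length(tr$times)
  expect_equal(profit(tr), tr$m[n] * tr$V[n])
  tr$m[n] <- 0
  expect_identical(profit(tr), 0)
  # arithmetic: 0.1 g/L in 2 L is 0.2 g
  tr$m[n] <- 0.1; tr$V[n] <- 2
  expect_equal(profit(tr), 0.2)
  # final volume from the feed integral alone
  expect_equal(design_final_volume(fed, c(0, 130), V0 = 1),
               1 + 0.02 * 130)
})

test_that("sparse community generator controls sparsity exactly", {
  ds <- generate_sparse_communities(n_total_species = 8, subset_size = 3,
                                    n_communities = 12, n_r = 5,
                                    seed = 3)
  expect_identical(length(ds), 12L)
  subsets <- attr(ds, "subsets")
  keys <- vapply(subsets, paste, character(1), collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  for (i in seq_len(12)) {
    s0 <- ds$conditions[[i]]$s0
    expect_identical(sum(s0 > 0), 3L)
    # absent species identically zero at every observed time point
    expect_true(all(ds$observations[[i]][, s0 == 0] == 0))
  }
  # full communities when the subset is the whole pool
  full <- generate_sparse_communities(n_total_species = 4,
                                      subset_size = 4,
                                      n_communities = 1, n_r = 3,
                                      seed = 1)
  expect_true(all(full$conditions[[1]]$s0 > 0))
  expect_error(generate_sparse_communities(n_total_species = 4,
                                           subset_size = 2,
                                           n_communities = 10,
                                           n_r = 3),
               "distinct")
})

test_that("fifty subsets of five from twenty are pairwise distinct", {
  ds <- generate_sparse_communities(n_total_species = 20,
                                    subset_size = 5,
                                    n_communities = 50, n_r = 10,
                                    seed = 0, noise_pct = 0,
                                    t_grid = c(0, 26))
  keys <- vapply(attr(ds, "subsets"), paste, character(1),
                 collapse = ",")
  expect_identical(length(unique(keys)), 50L)
})
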