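#' @title Fed-batch consumer-resource bioreactor (ground truth)
#' @description
#' A mechanistic consumer-resource community in a fed-batch bioreactor:
#' species grow by consuming shared resources (inducing competition), one
#' producer species converts growth into a target metabolite with
#' growth-associated kinetics, the feed adds volume and resources, and
#' nothing leaves the reactor. Governing equations:
#' \deqn{dV/dt = u}
#' \deqn{dr/dt = r \odot (-s^T C - d) + (u/V)(r_f - r)}
#' \deqn{ds/dt = s \odot (C r - g) - (u/V) s}
#' \deqn{dm/dt = y_{m/s}^T \max(0, ds/dt) - k_d m - (u/V) m}
#' @name bioreactor
NULL

#' Sample a random ground-truth ecosystem
#'
#' Species-resource dependence is Bernoulli with probability `p_sr`; the
#' concentration-parameter matrix is row-normalised so each species'
#' dependencies sum to one, and consumption rates are drawn around it
#' with 10% relative spread (truncated at zero). A species that draws no
#' resources at all is resampled (and the event logged). The single
#' producer species is the one depending on the fewest resources (ties to
#' the lowest index), with yield 0.5 — depending on few resources keeps
#' the optimal feed from being simply "all resources".
#'
#' @param n_s number of species.
#' @param n_r number of resources.
#' @param p_sr probability a species depends on a resource (default 0.6).
#' @param seed integer seed; identical seeds give identical ecosystems.
#' @param d_rate resource degradation rate (1/h), applied to all
#'   resources.
#' @param g_rate minimum growth rate (1/h), applied to all species.
#' @param k_d product degradation rate (1/h).
#' @param yield metabolite yield of the producer species.
#' @return Object of class `bioreactor_params` with fields `C` (n_s x
#'   n_r), `Theta`, `d`, `g`, `y_ms`, `k_d`, `p_sr`, `producer`, `seed`.
#' @export
sample_ecosystem <- function(n_s, n_r, p_sr = 0.6, seed = 0L,
                             d_rate = 0.01, g_rate = 0.01, k_d = 0.005,
                             yield = 0.5) {
  stopifnot(n_s >= 1, n_r >= 1, p_sr > 0, p_sr <= 1)
  resampled <- 0L
  out <- with_seed(seed, {
    Theta_raw <- matrix(stats::runif(n_s * n_r), n_s, n_r) *
      matrix(stats::rbinom(n_s * n_r, 1, p_sr), n_s, n_r)
    for (i in seq_len(n_s)) {
      while (all(Theta_raw[i, ] == 0)) {
        resampled <<- resampled + 1L
        Theta_raw[i, ] <- stats::runif(n_r) * stats::rbinom(n_r, 1, p_sr)
      }
    }
    Theta <- Theta_raw / rowSums(Theta_raw)
    C <- matrix(stats::rnorm(n_s * n_r, mean = Theta, sd = Theta / 10),
                n_s, n_r)
    C <- pmax(C, 0)
    list(Theta = Theta, C = C)
  })
  if (resampled > 0) {
    message(sprintf("resampled %d species with no resource dependence",
                    resampled))
  }
  producer <- which.min(rowSums(out$Theta > 0))
  y_ms <- rep(0, n_s)
  y_ms[producer] <- yield
  structure(list(C = out$C, Theta = out$Theta,
                 d = rep(d_rate, n_r), g = rep(g_rate, n_s),
                 y_ms = y_ms, k_d = k_d, p_sr = p_sr,
                 producer = producer, n_s = n_s, n_r = n_r,
                 seed = as.integer(seed)),
            class = "bioreactor_params")
}

#' Catalog of piecewise-constant feed-rate profiles
#'
#' Profiles are piecewise constant over `n_intervals` equal intervals of
#' the batch horizon, with rates drawn from a small grid and filtered to
#' distinct, non-identically-zero profiles; a seeded sample of
#' `n_profiles` of them forms the catalog.
#'
#' @param n_profiles number of profiles to return.
#' @param rates candidate feed rates (L/h) per interval.
#' @param n_intervals number of equal intervals.
#' @param seed seed for the catalog draw.
#' @return `n_profiles x n_intervals` matrix of feed rates.
#' @export
feed_profile_catalog <- function(n_profiles = 20L,
                                 rates = c(0, 0.005, 0.02),
                                 n_intervals = 5L, seed = 7L) {
  grid <- as.matrix(expand.grid(rep(list(rates), n_intervals)))
  colnames(grid) <- NULL
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  if (nrow(grid) < n_profiles) {
    stop("rate grid yields fewer distinct profiles than requested")
  }
  idx <- with_seed(seed, sample.int(nrow(grid), n_profiles))
  grid[idx, , drop = FALSE]
}

#' Enumerate the resource-subset x feed-profile design space
#'
#' The Cartesian product of all `2^n_r - 1` non-empty resource subsets
#' with every catalog profile, in deterministic order (subset bitmask
#' ascending, then profile index).
#'
#' @param n_r number of resources.
#' @param profile_catalog matrix of feed profiles (rows are profiles),
#'   e.g. from [feed_profile_catalog()].
#' @return Object of class `bioreactor_design_space`: list with
#'   `designs` (list of `list(resource_mask, feed_profile)`), `meta`
#'   (data.frame with `config_id`, `resource_bitmask`,
#'   `feed_profile_id`), `n_r` and `catalog`.
#' @export
enumerate_design_space <- function(n_r, profile_catalog) {
  stopifnot(n_r >= 1, nrow(profile_catalog) >= 1)
  n_subsets <- 2L^n_r - 1L
  n_prof <- nrow(profile_catalog)
  designs <- vector("list", n_subsets * n_prof)
  meta <- data.frame(config_id = integer(n_subsets * n_prof),
                     resource_bitmask = integer(n_subsets * n_prof),
                     feed_profile_id = integer(n_subsets * n_prof))
  k <- 0L
  for (mask_int in seq_len(n_subsets)) {
    mask <- as.integer(intToBits(mask_int))[seq_len(n_r)]
    for (p in seq_len(n_prof)) {
      k <- k + 1L
      designs[[k]] <- list(resource_mask = mask,
                           feed_profile = profile_catalog[p, ])
      meta$config_id[k] <- k
      meta$resource_bitmask[k] <- mask_int
      meta$feed_profile_id[k] <- p
    }
  }
  structure(list(designs = designs, meta = meta, n_r = n_r,
                 catalog = profile_catalog),
            class = "bioreactor_design_space")
}

#' @export
print.bioreactor_design_space <- function(x, ...) {
  cat(sprintf(
    "Bioreactor design space: %d resources x %d profiles = %d configurations\n",
    x$n_r, nrow(x$catalog), length(x$designs)))
  invisible(x)
}

# Feed rate at time t for a piecewise-constant profile over [t0, t_end].
feed_rate_at <- function(times, feed_profile, t0, t_end) {
  n_int <- length(feed_profile)
  breaks <- seq(t0, t_end, length.out = n_int + 1L)
  idx <- pmin(pmax(findInterval(times, breaks, rightmost.closed = TRUE),
                   1L), n_int)
  feed_profile[idx]
}

#' Simulate the fed-batch bioreactor
#'
#' Integrates the governing equations with `deSolve::ode` (lsoda,
#' rtol 1e-6 / atol 1e-9), segment by segment over the piecewise-constant
#' feed intervals, flooring the state at zero between segments. Recorded
#' species and metabolite observations at `t_grid` points after time zero
#' are corrupted with multiplicative Gaussian noise (`value * (1 + e)`,
#' `e ~ N(0, noise_pct)`) and clipped at zero, mimicking measurement
#' variation.
#'
#' @param params a `bioreactor_params` ecosystem.
#' @param design `list(resource_mask, feed_profile)`; `resource_mask`
#'   selects which resources appear in the feed, `feed_profile` gives the
#'   feed rate (L/h) on equal intervals of the horizon. Use a zero
#'   profile for batch operation.
#' @param V0 initial volume (L).
#' @param s0 initial species abundances (scalar recycled or length
#'   `n_s`).
#' @param r0 initial resource concentrations (scalar recycled or length
#'   `n_r`); the fed-batch default is 0 so the feed is the sole resource
#'   input.
#' @param m0 initial product concentration.
#' @param t_grid uniform observation times (hours).
#' @param rf_conc feed concentration (g/L) of each selected resource.
#' @param noise_pct relative standard deviation of measurement noise;
#'   0 disables noise.
#' @param seed seed for the noise draws.
#' @param rtol,atol integrator tolerances.
#' @return Object of class `bioreactor_trajectory`: `times`, noiseless
#'   states `V`, `r`, `s`, `m`, and noisy observations `s_obs`, `m_obs`.
#' @export
simulate_bioreactor <- function(params, design, V0 = 1, s0 = 0.01,
                                r0 = 0, m0 = 0,
                                t_grid = seq(0, 130, by = 26),
                                rf_conc = 1, noise_pct = 0.05,
                                seed = 0L, rtol = 1e-6, atol = 1e-9) {
  n_s <- params$n_s; n_r <- params$n_r
  stopifnot(V0 > 0)
  t_grid <- as.numeric(t_grid)
  s0 <- rep_len(s0, n_s); r0 <- rep_len(r0, n_r)
  r_f <- rf_conc * rep_len(design$resource_mask, n_r)
  profile <- design$feed_profile
  n_int <- length(profile)
  breaks <- seq(t_grid[1], t_grid[length(t_grid)],
                length.out = n_int + 1L)

  deriv <- function(t, x, parms) {
    V <- max(x[1], 1e-12)
    r <- pmax(x[2:(1 + n_r)], 0)
    s <- pmax(x[(2 + n_r):(1 + n_r + n_s)], 0)
    m <- max(x[2 + n_r + n_s], 0)
    u <- parms$u
    dV <- u
    dr <- r * (-as.numeric(crossprod(params$C, s)) - params$d) +
      (u / V) * (r_f - r)
    ds <- s * (as.numeric(params$C %*% r) - params$g) - (u / V) * s
    dm <- sum(params$y_ms * pmax(ds, 0)) - params$k_d * m - (u / V) * m
    list(c(dV, dr, ds, dm))
  }

  # segment boundaries: union of feed breakpoints and observation times
  seg_pts <- sort(unique(c(breaks, t_grid)))
  state <- c(V0, r0, s0, m0)
  rec <- matrix(NA_real_, length(t_grid), length(state))
  rec[1, ] <- state
  for (k in seq_len(length(seg_pts) - 1L)) {
    t_a <- seg_pts[k]; t_b <- seg_pts[k + 1L]
    u_k <- feed_rate_at((t_a + t_b) / 2, profile, breaks[1],
                        breaks[n_int + 1L])
    sol <- tryCatch(
      deSolve::ode(y = state, times = c(t_a, t_b), func = deriv,
                   parms = list(u = u_k), method = "lsoda",
                   rtol = rtol, atol = atol),
      error = function(e) stop(sprintf(
        "integration failed for design (bitmask context) at t = %.1f: %s",
        t_a, conditionMessage(e))))
    state <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    hit <- which(abs(t_grid - t_b) < 1e-9)
    if (length(hit)) rec[hit, ] <- state
  }

  V <- rec[, 1]
  r <- rec[, 2:(1 + n_r), drop = FALSE]
  s <- rec[, (2 + n_r):(1 + n_r + n_s), drop = FALSE]
  m <- rec[, 2 + n_r + n_s]
  s_obs <- s; m_obs <- m
  if (noise_pct > 0) {
    noisy <- with_seed(seed, {
      eps_s <- matrix(stats::rnorm(length(s), sd = noise_pct),
                      nrow(s), ncol(s))
      eps_m <- stats::rnorm(length(m), sd = noise_pct)
      list(s = s * (1 + eps_s), m = m * (1 + eps_m))
    })
    s_obs <- pmax(noisy$s, 0); m_obs <- pmax(noisy$m, 0)
    s_obs[1, ] <- s[1, ]; m_obs[1] <- m[1]  # t0 is a design, not a reading
  }
  structure(list(times = t_grid, V = V, r = r, s = s, m = m,
                 s_obs = s_obs, m_obs = m_obs, design = design),
            class = "bioreactor_trajectory")
}

#' Profit of a bioreactor run
#'
#' Total product mass at the end of the batch: final metabolite
#' concentration times final reactor volume (grams).
#'
#' @param trajectory a `bioreactor_trajectory`.
#' @param observed use the noisy observed metabolite reading (`TRUE`,
#'   what an experimenter would record) or the noiseless state.
#' @return Scalar profit in grams.
#' @export
profit <- function(trajectory, observed = FALSE) {
  n <- length(trajectory$times)
  m_T <- if (observed) trajectory$m_obs[n] else trajectory$m[n]
  m_T * trajectory$V[n]
}

#' Final reactor volume implied by a feed design
#'
#' Volume evolves as `dV/dt = u` independently of the community, so the
#' final volume is `V0` plus the integral of the piecewise-constant feed
#' profile. Used to convert model-predicted end-point concentrations into
#' predicted product mass.
#'
#' @inheritParams simulate_bioreactor
#' @param t_span `c(t0, t_end)` of the batch.
#' @return Final volume in litres.
#' @export
design_final_volume <- function(design, t_span = c(0, 130), V0 = 1) {
  n_int <- length(design$feed_profile)
  dt <- diff(t_span) / n_int
  V0 + sum(design$feed_profile * dt)
}

#' Convert a bioreactor design to a MiRNN experimental condition
#'
#' Controls presented to the model are the feed rate at each sampling
#' time plus the (static) feed resource concentrations, giving
#' `n_u = 1 + n_r` control inputs.
#'
#' @inheritParams simulate_bioreactor
#' @param id optional condition identifier.
#' @return A [mirnn_condition()] (original, unscaled units).
#' @export
design_to_condition <- function(design, t_grid = seq(0, 130, by = 26),
                                s0 = 0.01, m0 = 0, n_s = NULL,
                                rf_conc = 1, id = NULL) {
  if (is.null(n_s)) stop("n_s is required to size the initial state")
  n_int <- length(design$feed_profile)
  u_t <- feed_rate_at(pmin(t_grid + 1e-9, t_grid[length(t_grid)]),
                      design$feed_profile, t_grid[1],
                      t_grid[length(t_grid)])
  rf <- rf_conc * design$resource_mask
  controls <- cbind(u_t, matrix(rf, nrow = length(t_grid),
                                ncol = length(rf), byrow = TRUE))
  mirnn_condition(s0 = rep_len(s0, n_s), m0 = m0, controls = controls,
                  times = t_grid, id = id)
}

#' Trajectory observations as a dataset entry
#'
#' Packs the noisy species and metabolite observations of a simulated
#' trajectory into the `n_tau x n_y` observation matrix a
#' [mirnn_dataset()] expects.
#'
#' @param trajectory a `bioreactor_trajectory`.
#' @param include_metabolite include the product concentration column.
#' @return Matrix with `n_tau` rows.
#' @export
trajectory_observations <- function(trajectory, include_metabolite = TRUE) {
  obs <- trajectory$s_obs[-1, , drop = FALSE]
  if (include_metabolite) obs <- cbind(obs, trajectory$m_obs[-1])
  unname(obs)
}

#' Generate the sparse synthetic community datasets
#'
#' Emulates the sparsity study: random distinct subsets of `subset_size`
#' of `n_total_species` species, each grown in batch mode (no feed) from
#' equal initial abundances on a shared random ecosystem, observed at the
#' `t_grid` times with multiplicative noise. Absent species are
#' identically zero at every time point — the sparsity the constrained
#' model is built to exploit.
#'
#' @param n_total_species total species pool (e.g. 20).
#' @param subset_size species per community (e.g. 5, 10 or 15).
#' @param n_communities number of communities (e.g. 50).
#' @param t_grid uniform observation times.
#' @param seed master seed (ecosystem, subsets and noise all derive from
#'   it).
#' @param n_r number of resources of the ground-truth ecosystem.
#' @param params optional pre-sampled `bioreactor_params` (overrides
#'   `n_r`/seed-derived ecosystem).
#' @param s0_abund initial abundance of each present species.
#' @param r0 initial resource concentrations (batch mode needs resources
#'   present at time zero).
#' @param noise_pct measurement noise level.
#' @param include_metabolite include the product as an observed output.
#' @return A [mirnn_dataset()]; attribute `"subsets"` records the species
#'   index sets, attribute `"ecosystem"` the ground truth.
#' @export
generate_sparse_communities <- function(n_total_species = 20L,
                                        subset_size = 5L,
                                        n_communities = 50L,
                                        t_grid = seq(0, 130, by = 26),
                                        seed = 0L, n_r = 10L,
                                        params = NULL, s0_abund = 0.01,
                                        r0 = 1, noise_pct = 0.05,
                                        include_metabolite = FALSE) {
  stopifnot(subset_size <= n_total_species)
  if (choose(n_total_species, subset_size) < n_communities) {
    stop("fewer distinct subsets exist than communities requested")
  }
  seeds <- derive_seeds(seed, 2L + n_communities)
  if (is.null(params)) {
    params <- sample_ecosystem(n_total_species, n_r, seed = seeds[1])
  }
  subsets <- with_seed(seeds[2], {
    seen <- character(0)
    out <- list()
    while (length(out) < n_communities) {
      sub <- sort(sample.int(n_total_species, subset_size))
      key <- paste(sub, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- sub
      }
    }
    out
  })
  batch <- list(resource_mask = rep(1L, params$n_r),
                feed_profile = rep(0, 5L))
  conditions <- vector("list", n_communities)
  observations <- vector("list", n_communities)
  for (i in seq_len(n_communities)) {
    s0 <- rep(0, n_total_species)
    s0[subsets[[i]]] <- s0_abund
    traj <- simulate_bioreactor(params, batch, s0 = s0, r0 = r0,
                                t_grid = t_grid, noise_pct = noise_pct,
                                seed = seeds[2L + i])
    obs <- trajectory_observations(traj, include_metabolite)
    obs[, which(s0 == 0)] <- 0  # absent species identically zero
    conditions[[i]] <- mirnn_condition(
      s0 = s0, m0 = if (include_metabolite) 0 else numeric(0),
      controls = matrix(0, length(t_grid), 0), times = t_grid,
      id = sprintf("community_%02d", i))
    observations[[i]] <- obs
  }
  dims <- mirnn_dims(n_s = n_total_species,
                     n_m = if (include_metabolite) 1L else 0L,
                     n_u = 0L, n_h = 16L,
                     n_tau = length(t_grid) - 1L)
  ds <- mirnn_dataset(conditions, observations, dims)
  attr(ds, "subsets") <- subsets
  attr(ds, "ecosystem") <- params
  ds
}
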