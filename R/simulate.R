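# Deterministic simulation to equilibrium, with extinction thresholding,
# plus the two multispecies experiments: simultaneous start (richness) and
# sequential introduction (assembly).

#' Simulation controls
#'
#' @param extinction_threshold density below which a species is declared
#'   extinct and set to exactly 0 at the end of an integration window
#'   (default `1e-3`). Use 0 to disable pruning (e.g. for basin probing).
#' @param window_length length of one integration window in scaled time
#'   units (default 1000).
#' @param max_time total time budget; reaching it without meeting the
#'   convergence criterion sets `converged = FALSE` (default `1e6`).
#' @param conv_tol convergence criterion: converged when
#'   `max |dn_i/dt| < conv_tol` over surviving species (default `1e-9`).
#' @param rtol,atol relative/absolute integrator tolerances (defaults
#'   `1e-10` / `1e-12`; positive density dependence creates slow manifolds
#'   near the extinction threshold, so tolerances are kept tight).
#' @param record_trajectory keep the state at every window boundary.
#' @return a list of controls.
#' @export
sim_controls <- function(extinction_threshold = 1e-3, window_length = 1000,
                         max_time = 1e6, conv_tol = 1e-9, rtol = 1e-10,
                         atol = 1e-12, record_trajectory = FALSE) {
  stopifnot(extinction_threshold >= 0, window_length > 0,
            max_time >= window_length, conv_tol > 0, rtol > 0, atol > 0)
  list(extinction_threshold = extinction_threshold,
       window_length = window_length, max_time = max_time,
       conv_tol = conv_tol, rtol = rtol, atol = atol,
       record_trajectory = record_trajectory)
}

#' Integrate a community to equilibrium
#'
#' Integrates in windows; after each window every species whose density has
#' fallen below the extinction threshold is set to exactly 0 (extinction is
#' absorbing: a species at 0 has derivative exactly 0 and never returns).
#' Convergence is declared when the largest absolute rate of change over
#' surviving species drops below `conv_tol`.
#'
#' @param params a [community_params()] (use [embed_two_species()] for the
#'   two-species systems).
#' @param init vector of nonnegative initial densities.
#' @param controls a [sim_controls()] list.
#' @return a list with `state` (final densities), `time` (time reached),
#'   `converged`, `extinctions` (data frame of species index and window time
#'   of each pruning event), and, if requested, `times`/`states` at window
#'   boundaries.
#' @export
run_to_equilibrium <- function(params, init, controls = sim_controls()) {
  stopifnot(inherits(params, "community_params"))
  check_state(init, params$N)
  n <- as.numeric(init)
  t <- 0
  ext_sp <- integer(0); ext_t <- numeric(0)
  times <- t; states <- list(n)
  converged <- FALSE
  repeat {
    res <- integrate_window(params, n, controls$window_length,
                            rtol = controls$rtol, atol = controls$atol)
    if (!isTRUE(res$success))
      stop(sprintf("integrator failed at t=%g (state: %s)", t + res$t,
                   paste(signif(res$y, 6), collapse = ", ")), call. = FALSE)
    n <- res$y
    t <- t + controls$window_length
    dead <- integer(0)
    if (controls$extinction_threshold > 0) {
      dead <- which(n > 0 & n < controls$extinction_threshold)
      if (length(dead)) {
        n[dead] <- 0
        ext_sp <- c(ext_sp, dead); ext_t <- c(ext_t, rep(t, length(dead)))
      }
    }
    if (controls$record_trajectory) {
      times <- c(times, t); states <- c(states, list(n))
    }
    # zeros have derivative exactly 0, so this max is over survivors
    dy <- if (length(dead)) max(abs(evaluate_rhs(params, n))) else res$max_abs_rhs
    if (dy < controls$conv_tol) { converged <- TRUE; break }
    if (t >= controls$max_time) break
  }
  out <- list(state = n, time = t, converged = converged,
              extinctions = data.frame(species = ext_sp, time = ext_t))
  if (controls$record_trajectory) {
    out$times <- times
    out$states <- do.call(rbind, states)
  }
  out
}

# Stability of the surviving subcommunity at a converged state: all real
# parts of the Jacobian eigenvalues negative.
surviving_community_stable <- function(params, state, margin = 0) {
  alive <- which(state > 0)
  if (length(alive) == 0L) return(TRUE)
  sub <- subset_community(params, alive)
  J <- rhs_jacobian(sub, state[alive])
  max(Re(eigen(J, only.values = TRUE)$values)) < -margin
}

#' Simultaneous-start richness experiment
#'
#' For each seeded species pool and each density-dependence factor `s`, all
#' species start at density 1, the community is integrated to equilibrium
#' with extinction thresholding, and the number of surviving species is
#' recorded together with convergence and local-stability flags.
#'
#' @param config a [pool_config()].
#' @param n_pools number of pools (pool k is reproducible in isolation).
#' @param s_values vector of density-dependence factors to apply to every
#'   species.
#' @param controls a [sim_controls()] list.
#' @return a data frame with columns `pool_id`, `seed`, `scenario`, `s`,
#'   `final_richness`, `converged`, `stable`.
#' @export
richness_experiment <- function(config, n_pools, s_values,
                                controls = sim_controls()) {
  stopifnot(n_pools >= 1)
  rows <- vector("list", n_pools * length(s_values))
  idx <- 1L
  for (k in seq_len(n_pools)) {
    pool <- generate_pool(config, k)
    for (s in s_values) {
      params <- set_density_dependence(pool, s)
      sim <- run_to_equilibrium(params, rep(1, params$N), controls)
      rows[[idx]] <- data.frame(
        pool_id = k, seed = attr(pool, "child_seed"),
        scenario = config$scenario, s = s,
        final_richness = sum(sim$state > 0),
        converged = sim$converged,
        stable = sim$converged && surviving_community_stable(params, sim$state))
      idx <- idx + 1L
    }
  }
  do.call(rbind, rows)
}

#' Sequential-assembly experiment
#'
#' Species are introduced one at a time, in a seeded random order, at a low
#' introduction density; after each introduction the community is run to
#' equilibrium before the next species arrives. Final richness is recorded
#' after the last species has equilibrated. Because invaders start rare,
#' positive density dependence works against them here, in contrast to the
#' simultaneous start of [richness_experiment()].
#'
#' @inheritParams richness_experiment
#' @param intro_density introduction density; must exceed the extinction
#'   threshold (default `1e-2`, an order of magnitude above it).
#' @param intro_order_seed seed for the introduction orders; defaults to the
#'   pool config seed.
#' @return a data frame as in [richness_experiment()].
#' @export
assembly_experiment <- function(config, n_pools, s_values,
                                intro_density = 1e-2,
                                intro_order_seed = NULL,
                                controls = sim_controls()) {
  stopifnot(n_pools >= 1)
  if (intro_density <= controls$extinction_threshold)
    stop("`intro_density` must exceed the extinction threshold",
         call. = FALSE)
  if (is.null(intro_order_seed)) intro_order_seed <- config$seed
  rows <- vector("list", n_pools * length(s_values))
  idx <- 1L
  for (k in seq_len(n_pools)) {
    pool <- generate_pool(config, k)
    order_k <- with_seed(derive_seed(intro_order_seed, k),
                         sample.int(pool$N))
    for (s in s_values) {
      params <- set_density_dependence(pool, s)
      n <- numeric(params$N)
      converged <- TRUE
      for (sp in order_k) {
        n[sp] <- intro_density
        sim <- run_to_equilibrium(params, n, controls)
        n <- sim$state
        converged <- converged && sim$converged
      }
      rows[[idx]] <- data.frame(
        pool_id = k, seed = attr(pool, "child_seed"),
        scenario = config$scenario, s = s,
        final_richness = sum(n > 0),
        converged = converged,
        stable = converged && surviving_community_stable(params, n))
      idx <- idx + 1L
    }
  }
  do.call(rbind, rows)
}
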