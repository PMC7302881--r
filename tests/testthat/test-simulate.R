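# Integration to equilibrium, extinction thresholding, and the two
# multispecies experiments.

one_species <- function(d, s) {
  community_params(comp = matrix(1, 1, 1), d = d,
                   mortality = mortality_spec("hyperbolic", s))
}

test_that("a lone species reaches its effective carrying capacity", {
  sim <- run_to_equilibrium(one_species(0, 3), 0.01)
  expect_true(sim$converged)
  expect_equal(sim$state, 1, tolerance = 1e-8)
  # cross-module oracle: the closed-form quadratic root
  sim2 <- run_to_equilibrium(one_species(0.5, 1), 1)
  expect_true(sim2$converged)
  expect_equal(sim2$state, sqrt(0.5), tolerance = 1e-8)
})

test_that("the embedded two-species system converges to the located interior equilibrium", {
  p <- two_species_params("asym_competition", d = 0.9, alpha1 = 0.5,
                          mortality = mortality_spec("hyperbolic", 0.2))
  eqs <- find_equilibria(p)
  stable_int <- Filter(function(r) r$feasible && r$locally_stable, eqs)
  expect_length(stable_int, 1L)
  sim <- run_to_equilibrium(embed_two_species(p), c(1, 1),
                            sim_controls(extinction_threshold = 0))
  expect_true(sim$converged)
  expect_equal(sim$state, stable_int[[1]]$location, tolerance = 1e-6)
})

test_that("the R and C++ integrators agree", {
  set.seed(13)
  cp <- random_community(N = 4, s = 5)
  y0 <- runif(4, 0.2, 1)
  a <- cpdd:::integrate_window(cp, y0, 50)
  b <- cpdd:::integrate_window_r(cp, y0, 50)
  expect_true(a$success && b$success)
  expect_equal(a$y, b$y, tolerance = 1e-8)
})

test_that("registry mortality kinds fall back to the R integrator", {
  register_mortality_kind("test-sim-gaussian",
                          D = function(n, s, ref) exp(-s * n^2))
  cp <- community_params(comp = matrix(1, 1, 1), d = 0.5,
                         mortality = mortality_spec("test-sim-gaussian", 2))
  sim <- run_to_equilibrium(cp, 1, sim_controls(max_time = 2e4))
  expect_true(sim$converged)
  expect_lt(abs(1 - sim$state - 0.5 * exp(-2 * sim$state^2)), 1e-8)
})

test_that("extinction is declared below threshold and is absorbing", {
  # species 2 pays delta = 1: effective mortality 1, negative growth even
  # alone at low density when s = 0, so it is always excluded
  cp <- community_params(comp = diag(1, 3), delta = c(0, 1, 0), d = 0.5)
  sim <- run_to_equilibrium(cp, rep(1, 3),
                            sim_controls(record_trajectory = TRUE))
  expect_true(sim$converged)
  expect_identical(sim$state[2], 0)
  expect_equal(sim$state[c(1, 3)], c(0.5, 0.5), tolerance = 1e-8)
  expect_identical(sim$extinctions$species, 2L)
  # non-negativity along the trajectory, and 0 stays 0
  expect_true(all(sim$states >= 0))
  ext_row <- match(sim$extinctions$time, sim$times)
  expect_true(all(sim$states[ext_row:nrow(sim$states), 2] == 0))
})

test_that("converged states are equilibria of the pruned system", {
  set.seed(17)
  for (rep in 1:5) {
    cp <- random_community(N = 10, s = 10^runif(1, -1, 4))
    sim <- run_to_equilibrium(cp, rep(1, 10))
    expect_true(sim$converged)
    expect_lt(max(abs(evaluate_rhs(cp, sim$state))), 1e-9)
    expect_true(all(sim$state >= 0))
    expect_true(cpdd:::surviving_community_stable(cp, sim$state))
  }
})

test_that("richness experiment: independent species all persist", {
  cfg <- pool_config(3, n_species = 6, symmetric_alpha = 0, delta_range = c(0, 0),
                     d = 0.5, seed = 1)
  df <- richness_experiment(cfg, n_pools = 2, s_values = c(0, 100))
  expect_true(all(df$final_richness == 6))
  expect_true(all(df$converged))
  expect_true(all(df$stable))
})

test_that("richness experiment is deterministic given the master seed", {
  cfg <- pool_config(4, n_species = 10, seed = 21)
  a <- richness_experiment(cfg, n_pools = 2, s_values = c(0, 1e4))
  b <- richness_experiment(cfg, n_pools = 2, s_values = c(0, 1e4))
  expect_identical(a, b)
})

test_that("assembly: no interactions means order cannot matter", {
  cfg <- pool_config(3, n_species = 5, symmetric_alpha = 0,
                     delta_range = c(0, 0), d = 0.5, seed = 9)
  df <- assembly_experiment(cfg, n_pools = 2, s_values = 0)
  expect_true(all(df$final_richness == 5))
})

test_that("assembly rejects introduction at or below the extinction threshold", {
  cfg <- pool_config(1, n_species = 4, seed = 1)
  expect_error(assembly_experiment(cfg, 1, 0, intro_density = 1e-3),
               "exceed the extinction threshold")
})

test_that("assembly never beats the simultaneous start at high s", {
  cfg <- pool_config(4, n_species = 12, seed = 33)
  sim <- richness_experiment(cfg, n_pools = 3, s_values = 1e4)
  asm <- assembly_experiment(cfg, n_pools = 3, s_values = 1e4)
  expect_true(all(asm$final_richness <= sim$final_richness))
})

test_that("negative initial densities are rejected", {
  expect_error(run_to_equilibrium(one_species(0.5, 1), -0.1), "nonnegative")
})
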