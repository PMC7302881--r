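# Equilibria, stability, invasion growth rates, and the tristate
# classification.

test_that("single-species equilibria match closed forms", {
  # constant mortality: logistic shifted to 1 - d
  r <- single_species_equilibria(0.4, mortality_spec("hyperbolic", 0))
  expect_equal(r$density, c(0, 0.6))
  expect_identical(r$stable, c(FALSE, TRUE))
  # no mortality: pure logistic
  r0 <- single_species_equilibria(0, mortality_spec("hyperbolic", 7))
  expect_equal(r0$density, c(0, 1))
  expect_true(r0$stable[2])
  # hyperbolic quadratic: m = 0.5, s = 1 -> n^2 - 0.5 = 0 -> sqrt(0.5)
  r1 <- single_species_equilibria(0.5, mortality_spec("hyperbolic", 1))
  expect_equal(r1$density[2], sqrt(0.5), tolerance = 1e-12)
  n <- r1$density[2]
  expect_lt(abs(1 - n - 0.5 / (1 + n)), 1e-12)
})

test_that("single-species equilibria agree with long ODE integration", {
  set.seed(11)
  for (rep in 1:8) {
    d <- runif(1, 0.05, 0.95)
    s <- 10^runif(1, -1, 3)
    r <- single_species_equilibria(d, mortality_spec("hyperbolic", s))
    stable <- r$density[r$density > 0 & r$stable]
    expect_length(stable, 1L)
    cp <- community_params(comp = matrix(1, 1, 1), d = d,
                           mortality = mortality_spec("hyperbolic", s))
    sim <- run_to_equilibrium(cp, 1, sim_controls(extinction_threshold = 0))
    expect_true(sim$converged)
    expect_equal(sim$state, stable, tolerance = 1e-6)
  }
})

test_that("non-hyperbolic kinds fall back on bracketed root finding", {
  r <- single_species_equilibria(0.5, mortality_spec("exponential", 2))
  stable <- r$density[r$density > 0 & r$stable]
  for (n in stable) expect_lt(abs(1 - n - 0.5 * exp(-2 * n)), 1e-10)
})

test_that("find_equilibria recovers closed-form equilibria", {
  p <- two_species_params("asym_competition", d = 0.5, alpha1 = 0.5)
  eqs <- find_equilibria(p)
  locs <- t(vapply(eqs, function(r) r$location, numeric(2)))
  expect_true(any(apply(locs, 1, function(x) max(abs(x - c(0.5, 0.25))) < 1e-9)))
  # all records verify residual < 1e-10 on re-evaluation
  for (r in eqs) expect_lt(max(abs(evaluate_rhs(p, r$location))), 1e-10)

  p0 <- two_species_params("asym_competition", d = 0, alpha1 = 0)
  eqs0 <- find_equilibria(p0)
  locs0 <- t(vapply(eqs0, function(r) r$location, numeric(2)))
  expect_true(any(apply(locs0, 1, function(x) max(abs(x - c(1, 1))) < 1e-9)))

  pr <- two_species_params("repro_interference", d = 0.2, alpha = 0.1,
                           alpha1p = 0.6,
                           mortality = mortality_spec("hyperbolic", 30))
  for (r in find_equilibria(pr))
    expect_lt(max(abs(evaluate_rhs(pr, r$location))), 1e-10)
})

test_that("jacobian matches analytic differentiation for the asymmetric model", {
  # analytic oracle: f1 = n1 (1 - n1 - d D(n1)), f2 = n2 (1 - n2 - a1 n1 - d D(n2))
  analytic <- function(p, n) {
    s <- p$mortality$s
    D <- function(x) 1 / (1 + s * x)
    Dp <- function(x) -s / (1 + s * x)^2
    matrix(c(1 - 2 * n[1] - p$d * (D(n[1]) + n[1] * Dp(n[1])), 0,
             -p$alpha1 * n[2],
             1 - 2 * n[2] - p$alpha1 * n[1] - p$d * (D(n[2]) + n[2] * Dp(n[2]))),
           2, 2, byrow = TRUE)
  }
  set.seed(3)
  for (rep in 1:100) {
    p <- random_two_species("asym_competition")
    n <- runif(2, 0.05, 1.2)
    expect_equal(rhs_jacobian(p, n), analytic(p, n), tolerance = 1e-5)
  }
  # s = 0 interior: species 1 insensitive to species 2 (triangular structure)
  p <- two_species_params("asym_competition", d = 0.5, alpha1 = 0.5)
  J <- rhs_jacobian(p, c(0.5, 0.25))
  expect_lt(abs(J[1, 2]), 1e-9)
  # stable single-species equilibrium has a negative 1x1 Jacobian
  cp <- community_params(comp = matrix(1, 1, 1), d = 0.5,
                         mortality = mortality_spec("hyperbolic", 1))
  expect_lt(rhs_jacobian(cp, sqrt(0.5))[1, 1], 0)
})

test_that("invasion growth rates match closed forms", {
  p <- two_species_params("asym_competition", d = 0.5, alpha1 = 0.5)
  # species 2 invading species 1 at its carrying capacity 1 - d, s = 0:
  # rate = 1 - alpha1 (1 - d) - d = (1 - d)(1 - alpha1)
  expect_equal(invasion_growth_rate(p, 2, c(0.5, 0)), 0.25, tolerance = 1e-12)
  # empty community: growth minus basal mortality
  expect_equal(invasion_growth_rate(p, 1, c(0, 0)), 0.5, tolerance = 1e-12)
  # interference: the rare invader's growth term vanishes entirely
  pr <- two_species_params("repro_interference", d = 0.2, alpha = 0.3,
                           alpha1p = 0.8)
  n1_star <- 0.8  # 1 - d with s = 0
  expect_equal(invasion_growth_rate(pr, 2, c(n1_star, 0)),
               -0.3 * n1_star - 0.2, tolerance = 1e-12)
  # non-equilibrium resident state is rejected
  expect_error(invasion_growth_rate(p, 2, c(0.123, 0)), "not an equilibrium")
  expect_error(invasion_growth_rate(p, 2, c(0.5, 0.25)), "absent")
})

test_that("invasion-rate sign agrees with direct simulation from rarity", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:200) {
    model <- sample(two_species_models, 1)
    p <- random_two_species(model)
    eqs <- find_equilibria(p)
    bnd <- Filter(function(r) r$locally_stable &&
                    sum(r$location == 0) == 1, eqs)
    if (!length(bnd)) next
    r <- bnd[[1]]
    i <- which(r$location == 0)
    rate <- invasion_growth_rate(p, i, r$location)
    if (abs(rate) < 1e-6) next
    # integrate from invader density 1e-6 over a horizon scaled to the
    # rate so even |rate| barely above the 1e-6 cutoff moves the invader
    # well beyond integration error
    n0 <- r$location; n0[i] <- 1e-6
    cp <- embed_two_species(p)
    horizon <- min(20 / abs(rate), 2e4)
    res <- cpdd:::integrate_window(cp, n0, horizon)
    grew <- res$y[i] > n0[i]
    expect_identical(grew, rate > 0)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("classification at s = 0 matches the Lotka-Volterra closed form", {
  set.seed(5)
  for (rep in 1:6) {
    d <- runif(1, 0, 0.9); a1 <- runif(1, 0, 0.9)
    p <- two_species_params("asym_competition", d = d, alpha1 = a1)
    cl <- classify_coexistence(p)
    expect_identical(cl$label, "global_attractor")
    expect_false(cl$inconclusive)
    expect_equal(cl$coexistence_eq$location,
                 c(1 - d, (1 - d) * (1 - a1)), tolerance = 1e-8)
  }
})

test_that("sweeping s upward yields the global -> none -> local sequence", {
  # reduced version of the Fig. 5 regimes; the full canonical grid with
  # grid-doubling stability is exercised in test-acceptance.R
  s_grid <- c(0, 10^seq(-2, 4, length.out = 16))
  labs <- vapply(s_grid, function(s) classify_coexistence(
    two_species_params("asym_competition", d = 0.9, alpha1 = 0.5,
                       mortality = mortality_spec("hyperbolic", s)))$label,
    character(1))
  expect_identical(rle(labs)$values,
                   c("global_attractor", "none", "local_attractor"))
})

test_that("asymmetric reproductive interference is never a global attractor", {
  for (a1p in c(0.2, 0.6, 1)) for (s in c(0, 1, 100, 1e4)) {
    cl <- classify_coexistence(
      two_species_params("repro_interference", d = 0.5, alpha = 0,
                         alpha1p = a1p,
                         mortality = mortality_spec("hyperbolic", s)))
    expect_true(cl$label %in% c("none", "local_attractor"))
  }
})

test_that("feasible interior equilibria keep the weaker species rarer", {
  set.seed(31)
  for (rep in 1:40) {
    p <- random_two_species("asym_competition")
    for (r in find_equilibria(p)) {
      if (r$feasible)
        expect_lte(r$location[2], r$location[1] + 1e-9)
    }
  }
})
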