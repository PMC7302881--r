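# Density-dependent mortality multipliers.

test_that("hyperbolic multiplier matches its closed form", {
  sp <- mortality_spec("hyperbolic", s = 1)
  expect_identical(evaluate_mortality(sp, 0), 1)
  expect_identical(evaluate_mortality(sp, 1), 0.5)
  # at extreme s, mortality is essentially gone at carrying capacity
  expect_equal(evaluate_mortality(mortality_spec("hyperbolic", 1e4), 1),
               1 / 10001, tolerance = 1e-12)
  expect_lt(evaluate_mortality(mortality_spec("hyperbolic", 1e4), 1), 1e-4)
})

test_that("density slope dD/dn is normalized to -s at n = 0", {
  expect_equal(mortality_density_slope(mortality_spec("hyperbolic", 3), 0), -3)
  expect_identical(mortality_density_slope(mortality_spec("hyperbolic", 0), 0.7), 0)
  expect_equal(mortality_density_slope(mortality_spec("hyperbolic", 1), 1), -0.25)
  # finite-difference check of the n = 0 normalization for all
  # density-dependent kinds, relative tolerance 1e-6
  for (kind in c("hyperbolic", "exponential", "linear")) {
    for (s in c(0.3, 2, 50)) {
      sp <- mortality_spec(kind, s)
      h <- 1e-9
      fd <- (evaluate_mortality(sp, h) - evaluate_mortality(sp, 0)) / h
      expect_equal(mortality_density_slope(sp, 0), fd, tolerance = 1e-6)
      expect_equal(mortality_density_slope(sp, 0), -s, tolerance = 1e-6)
    }
  }
})

test_that("factor sensitivity dD/ds matches analytic differentiation", {
  expect_identical(mortality_factor_sensitivity(mortality_spec("hyperbolic", 5), 0), 0)
  expect_equal(mortality_factor_sensitivity(mortality_spec("hyperbolic", 0), 2), -2)
  expect_equal(mortality_factor_sensitivity(mortality_spec("hyperbolic", 100), 1),
               -1 / 101^2)
  # central finite difference in s as independent oracle
  for (s in c(0.5, 10)) for (n in c(0.1, 1, 3)) {
    h <- 1e-6 * s
    fd <- (1 / (1 + (s + h) * n) - 1 / (1 + (s - h) * n)) / (2 * h)
    expect_equal(mortality_factor_sensitivity(mortality_spec("hyperbolic", s), n),
                 fd, tolerance = 1e-6)
  }
})

test_that("all kinds stay within [0, 1] and reduce to 1 at s = 0", {
  set.seed(101)
  kinds <- c("hyperbolic", "exponential", "linear",
             "density-independent-control")
  for (kind in kinds) {
    # 2500 draws per kind, 10^4 in total
    s <- 10^runif(2500, -3, 5)
    n <- 10^runif(2500, -4, 1)
    D <- mapply(function(si, ni)
      evaluate_mortality(mortality_spec(kind, si), ni), s, n)
    expect_true(all(D >= 0 & D <= 1))
    expect_true(all(mapply(function(ni)
      evaluate_mortality(mortality_spec(kind, 0), ni), n) == 1))
  }
  # normalization D(0) = 1 for the density-dependent kinds at any s
  for (kind in c("hyperbolic", "exponential", "linear"))
    for (s in c(0, 1, 1e4))
      expect_identical(evaluate_mortality(mortality_spec(kind, s), 0), 1)
})

test_that("hyperbolic dD/ds is unimodal in n with maximizer 1/s", {
  for (s in c(0.5, 2, 100)) {
    sp <- mortality_spec("hyperbolic", s)
    n_star <- 1 / s
    grid <- n_star * 10^seq(-2, 2, length.out = 41)
    mag <- abs(mortality_factor_sensitivity(sp, grid))
    peak <- which.max(mag)
    expect_equal(grid[peak], n_star, tolerance = 0.3)
    # strictly smaller magnitude on both flanks
    expect_true(all(diff(mag[seq_len(peak)]) > 0))
    expect_true(all(diff(mag[peak:length(mag)]) < 0))
    # whenever two densities bracket the maximizer from the same side order
    expect_gt(abs(mortality_factor_sensitivity(sp, n_star)),
              abs(mortality_factor_sensitivity(sp, 100 * n_star)))
  }
})

test_that("hyperbolic D is strictly decreasing for s > 0", {
  sp <- mortality_spec("hyperbolic", 2)
  n <- seq(0, 5, length.out = 200)
  expect_true(all(diff(evaluate_mortality(sp, n)) < 0))
})

test_that("invalid arguments are rejected", {
  expect_error(mortality_spec("hyperbolic", -1), "nonnegative")
  expect_error(evaluate_mortality(mortality_spec(), -0.1), "nonnegative")
  expect_error(mortality_spec("no-such-kind"))
})

test_that("new kinds can be registered and used", {
  register_mortality_kind("test-gaussian",
                          D = function(n, s, ref) exp(-s * n^2))
  sp <- mortality_spec("test-gaussian", s = 2)
  expect_equal(evaluate_mortality(sp, 1), exp(-2))
  # finite-difference fallbacks for derivatives
  expect_equal(mortality_density_slope(sp, 1), -2 * 2 * 1 * exp(-2),
               tolerance = 1e-5)
  expect_equal(mortality_factor_sensitivity(sp, 1), -exp(-2),
               tolerance = 1e-5)
})
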