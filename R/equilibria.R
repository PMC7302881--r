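# Equilibrium location, feasibility, local stability, invasion growth rates,
# and the tristate classification of two-species coexistence:
# none / local attractor / global attractor.
#
# A coexistence equilibrium is "feasible" when all densities exceed the
# feasibility tolerance, "locally stable" when all Jacobian eigenvalues have
# real part below -stability margin. It is a *global* attractor when it is
# reached from every positive initial condition; operationally: (a) every
# missing species has a positive invasion growth rate at every locally
# stable boundary attractor, and (b) trajectories from a fixed probe grid of
# initial conditions all converge to it. Otherwise it is a *local*
# attractor (typically not reached when the least competitive species starts
# rare).

#' Classification controls
#'
#' @param feasibility_tol a density counts as positive above this value
#'   (default `1e-6`: far below any meaningful density on the rescaled axis,
#'   far above root-finder noise).
#' @param stability_margin an equilibrium is locally stable if the largest
#'   eigenvalue real part is below `-stability_margin`; eigenvalues within
#'   the margin of 0 mark the record as marginal and the classification as
#'   inconclusive (default `1e-8`).
#' @param probe_grid per-axis initial densities of the basin probe grid.
#' @param probe_dist convergence radius (L-infinity) around the coexistence
#'   equilibrium (default `1e-4`).
#' @param root_tol max |dn/dt| allowed at a reported equilibrium
#'   (default `1e-10`).
#' @param sim [sim_controls()] used for probe integrations; extinction
#'   pruning is disabled there because classification concerns the
#'   continuous flow.
#' @export
classify_controls <- function(feasibility_tol = 1e-6,
                              stability_margin = 1e-8,
                              probe_grid = c(1e-4, 1e-2, 1e-1, 0.5, 1),
                              probe_dist = 1e-4,
                              root_tol = 1e-10,
                              sim = sim_controls(extinction_threshold = 0)) {
  list(feasibility_tol = feasibility_tol,
       stability_margin = stability_margin,
       probe_grid = probe_grid, probe_dist = probe_dist,
       root_tol = root_tol, sim = sim)
}

#' Single-species equilibria (effective carrying capacities)
#'
#' Roots of `1 - n - m * D(n) = 0` for a species alone with effective
#' mortality `m` (`m = d`, or `d + delta * (1 - d)` for a species paying the
#' basal-mortality increment), plus the trivial root `n = 0`. The stable
#' nonzero root is the effective carrying capacity: the density reached at
#' equilibrium without competitors. For hyperbolic mortality the nonzero
#' roots solve the quadratic `s n^2 + (1 - s) n + (m - 1) = 0` in closed
#' form; other kinds are handled by bracketed root finding.
#'
#' @param effective_mortality scalar `m` in \[0, 1\].
#' @param mortality a [mortality_spec()].
#' @return data frame with columns `density` and `stable`.
#' @export
single_species_equilibria <- function(effective_mortality,
                                      mortality = mortality_spec()) {
  m <- effective_mortality
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m > 1)
    stop("`effective_mortality` must be a single value in [0, 1]",
         call. = FALSE)
  s <- mortality$s
  roots <- numeric(0)
  if (mortality$kind == "hyperbolic" && s > 0) {
    # (1 - n)(1 + s n) - m = 0  =>  s n^2 + (1 - s) n + (m - 1) = 0
    disc <- (1 - s)^2 - 4 * s * (m - 1)
    if (disc >= 0) {
      r <- (-(1 - s) + c(-1, 1) * sqrt(disc)) / (2 * s)
      roots <- r[r > 0]
    }
  } else if (s == 0 || mortality$kind == "density-independent-control") {
    D0 <- evaluate_mortality(mortality, 0)
    if (1 - m * D0 > 0) roots <- 1 - m * D0
  } else {
    g <- function(n) 1 - n - m * evaluate_mortality(mortality, n)
    grid <- seq(0, 2, length.out = 2001)
    gv <- g(grid)
    sgn <- sign(gv)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    roots <- vapply(flips, function(i)
      uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-14)$root, numeric(1))
    roots <- sort(unique(c(roots, grid[gv == 0 & grid > 0])))
  }
  # per-capita growth g(n) = 1 - n - m D(n); a nonzero root is stable iff
  # g'(n) < 0; the origin is stable iff g(0) < 0.
  gprime <- -1 - m * mortality_density_slope(mortality, roots)
  data.frame(density = c(0, roots),
             stable = c(1 - m * evaluate_mortality(mortality, 0) < 0,
                        gprime < 0))
}

# Vectorized per-capita growth rates of a two-species system, as functions
# of (n1, n2) vectors. Only valid for positive densities (interior use).
per_capita_growth <- function(params) {
  d <- params$d
  D <- function(x) evaluate_mortality(params$mortality, x)
  switch(params$model,
    asym_competition = list(
      g1 = function(n1, n2) 1 - n1 - d * D(n1),
      g2 = function(n1, n2) 1 - n2 - params$alpha1 * n1 - d * D(n2)),
    basal_mortality = list(
      g1 = function(n1, n2) 1 - n1 - params$alpha * n2 - d * D(n1),
      g2 = function(n1, n2) 1 - n2 - params$alpha * n1 -
        (d + params$delta * (1 - d)) * D(n2)),
    repro_interference = list(
      g1 = function(n1, n2) 1 - n1 - params$alpha * n2 - d * D(n1),
      g2 = function(n1, n2) n2 / (params$alpha1p * n1 + n2) - n2 -
        params$alpha * n1 - d * D(n2)))
}

# Damped Newton iteration on the interior per-capita system, run
# simultaneously from all seeds (vectors n1, n2). Jacobians by forward
# differences; 2x2 solves done componentwise.
newton_interior <- function(params, n1, n2, max_iter = 80, gtol = 1e-13) {
  g <- per_capita_growth(params)
  for (it in seq_len(max_iter)) {
    f1 <- g$g1(n1, n2); f2 <- g$g2(n1, n2)
    if (all(pmax(abs(f1), abs(f2)) < gtol, na.rm = TRUE)) break
    h1 <- 1e-8 * pmax(1, n1); h2 <- 1e-8 * pmax(1, n2)
    a <- (g$g1(n1 + h1, n2) - f1) / h1; b <- (g$g1(n1, n2 + h2) - f1) / h2
    cc <- (g$g2(n1 + h1, n2) - f2) / h1; dd <- (g$g2(n1, n2 + h2) - f2) / h2
    det <- a * dd - b * cc
    det[det == 0 | !is.finite(det)] <- NA
    s1 <- (dd * f1 - b * f2) / det
    s2 <- (a * f2 - cc * f1) / det
    # keep iterates strictly inside the positive quadrant; park seeds whose
    # Newton step degenerated (singular Jacobian) at the corner, where they
    # will fail the residual filter
    n1 <- pmax(n1 - s1, 1e-12)
    n2 <- pmax(n2 - s2, 1e-12)
    bad <- !is.finite(n1) | !is.finite(n2)
    n1[bad] <- 1e-12
    n2[bad] <- 1e-12
  }
  f1 <- g$g1(n1, n2); f2 <- g$g2(n1, n2)
  ok <- is.finite(n1) & is.finite(n2) & pmax(abs(f1), abs(f2)) < 1e-11 &
    n1 > 1e-9 & n2 > 1e-9 & n1 < 10 & n2 < 10
  cbind(n1 = n1[ok], n2 = n2[ok])
}

# Build an equilibrium record: residual, feasibility, eigenvalues, local
# stability, marginality.
equilibrium_record <- function(params, location, controls) {
  rhs <- evaluate_rhs(params, location)
  J <- rhs_jacobian(params, location)
  ev <- Re(eigen(J, only.values = TRUE)$values)
  mx <- max(ev)
  list(location = location,
       residual = max(abs(rhs)),
       feasible = all(location > controls$feasibility_tol),
       eig_real_parts = ev,
       locally_stable = mx < -controls$stability_margin,
       marginal = abs(mx) <= controls$stability_margin)
}

#' Locate all equilibria of a two-species system
#'
#' Returns the origin, the boundary equilibria (one species absent, from the
#' closed-form or bracketed single-species roots), and the interior
#' equilibria found by multi-start Newton iteration on the per-capita system
#' seeded from a 12 x 12 log-spaced grid over (0, 1.5\]^2, deduplicated and
#' verified to residual below `root_tol`.
#'
#' @param params a [two_species_params()].
#' @param controls a [classify_controls()] list.
#' @return list of equilibrium records (`location`, `residual`, `feasible`,
#'   `eig_real_parts`, `locally_stable`, `marginal`).
#' @export
find_equilibria <- function(params, controls = classify_controls()) {
  stopifnot(inherits(params, "two_species_params"))
  locs <- list(c(0, 0))
  m1 <- params$d
  m2 <- params$d + (if (params$model == "basal_mortality") params$delta else 0) *
    (1 - params$d)
  r1 <- single_species_equilibria(m1, params$mortality)
  r2 <- single_species_equilibria(m2, params$mortality)
  for (r in r1$density[r1$density > 0]) locs <- c(locs, list(c(r, 0)))
  for (r in r2$density[r2$density > 0]) locs <- c(locs, list(c(0, r)))

  seeds <- 10^seq(log10(5e-4), log10(1.5), length.out = 12)
  grid <- expand.grid(n1 = seeds, n2 = seeds)
  interior <- newton_interior(params, grid$n1, grid$n2)
  if (nrow(interior)) {
    keep <- rep(TRUE, nrow(interior))
    for (i in seq_len(nrow(interior))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(interior))) {
        if (j > i && keep[j] &&
            max(abs(interior[i, ] - interior[j, ])) < 1e-6)
          keep[j] <- FALSE
      }
    }
    for (i in which(keep)) locs <- c(locs, list(unname(interior[i, ])))
  }
  recs <- lapply(locs, function(x) equilibrium_record(params, x, controls))
  recs[vapply(recs, function(r) r$residual < controls$root_tol, logical(1))]
}

#' Jacobian of the right-hand side at a point
#'
#' Central finite differences with step `1e-7 * max(1, |n_k|)` per
#' coordinate, switching to one-sided differences at boundary zeros (the
#' state space is the nonnegative orthant).
#'
#' @param params a [two_species_params()] or [community_params()].
#' @param location density vector with nonnegative coordinates.
#' @return a square matrix of partial derivatives.
#' @export
rhs_jacobian <- function(params, location) {
  if (any(location < 0)) stop("densities must be nonnegative", call. = FALSE)
  N <- length(location)
  J <- matrix(0, N, N)
  for (k in seq_len(N)) {
    h <- 1e-7 * max(1, abs(location[k]))
    up <- location; up[k] <- location[k] + h
    lo <- location; lo[k] <- location[k] - h
    if (lo[k] >= 0) {
      J[, k] <- (evaluate_rhs(params, up) - evaluate_rhs(params, lo)) / (2 * h)
    } else {
      J[, k] <- (evaluate_rhs(params, up) - evaluate_rhs(params, location)) / h
    }
  }
  J
}

#' Invasion growth rate of a rare species
#'
#' Per-capita growth rate of species `invader` in the limit of vanishing
#' density, with the residents at `resident_equilibrium`. The
#' reproductive-interference growth term tends to 0 in this limit whenever
#' any interfering resident has positive density (frequency dependence: a
#' rare species faces an unbounded heterospecific:conspecific ratio), and to
#' 1 when none has.
#'
#' @param params a [two_species_params()] or [community_params()].
#' @param invader species index (1-based).
#' @param resident_equilibrium density vector with the invader at 0; must be
#'   an equilibrium of the system (residual checked).
#' @return the per-capita growth rate; positive means invasion from rarity
#'   succeeds.
#' @export
invasion_growth_rate <- function(params, invader, resident_equilibrium) {
  cp <- if (inherits(params, "two_species_params"))
    embed_two_species(params) else params
  n <- as.numeric(resident_equilibrium)
  check_state(n, cp$N)
  if (n[invader] > 0)
    stop("invader must be absent from the resident equilibrium",
         call. = FALSE)
  if (max(abs(evaluate_rhs(cp, n))) > 1e-8)
    stop("`resident_equilibrium` is not an equilibrium (residual too large)",
         call. = FALSE)
  i <- invader
  others <- setdiff(seq_len(cp$N), i)
  ri_pressure <- sum(cp$ri[i, others] * n[others])
  growth_limit <- if (ri_pressure > 0) 0 else 1
  m <- cp$d + cp$delta[i] * (1 - cp$d)
  D0 <- evaluate_mortality(cp$mortality$specs[[i]], 0)
  growth_limit - sum(cp$comp[i, others] * n[others]) - m * D0
}

#' Classify two-species coexistence
#'
#' Tristate classification of the coexistence equilibrium:
#' \describe{
#'   \item{`none`}{no feasible, locally stable interior equilibrium.}
#'   \item{`global_attractor`}{the interior equilibrium is reached from
#'     every probed positive initial condition and every missing species can
#'     invade every locally stable boundary attractor.}
#'   \item{`local_attractor`}{a feasible locally stable interior equilibrium
#'     exists but is not reached from some positive initial conditions.}
#' }
#' Marginal eigenvalues (within the stability margin of zero) or
#' non-convergent probe trajectories make the classification inconclusive;
#' this is flagged, never silently resolved.
#'
#' @param params a [two_species_params()].
#' @param controls a [classify_controls()] list.
#' @return an object of class `coexistence_class`: list with `label`,
#'   `coexistence_eq`, `boundary_eqs`, `equilibria` (all records),
#'   `inconclusive`, `reason`.
#' @export
classify_coexistence <- function(params, controls = classify_controls()) {
  eqs <- find_equilibria(params, controls)
  is_boundary <- vapply(eqs, function(r)
    any(r$location <= controls$feasibility_tol), logical(1))
  interior <- eqs[!is_boundary]
  boundary <- eqs[is_boundary]

  inconclusive <- FALSE
  reason <- NULL
  if (any(vapply(eqs, function(r) r$marginal, logical(1)))) {
    inconclusive <- TRUE
    reason <- "marginal eigenvalue at an equilibrium"
  }

  stable_interior <- Filter(function(r) r$feasible && r$locally_stable,
                            interior)
  out <- function(label, coex = NULL) {
    structure(list(label = label, coexistence_eq = coex,
                   boundary_eqs = boundary, equilibria = eqs,
                   inconclusive = inconclusive, reason = reason),
              class = "coexistence_class")
  }
  if (length(stable_interior) == 0L) return(out("none"))
  if (length(stable_interior) > 1L) {
    inconclusive <- TRUE
    reason <- "multiple stable interior equilibria"
  }
  coex <- stable_interior[[1L]]

  # (a) invasion from rarity at every locally stable boundary attractor
  for (r in boundary) {
    if (!r$locally_stable) next
    for (i in which(r$location <= controls$feasibility_tol)) {
      loc <- r$location
      loc[i] <- 0
      if (invasion_growth_rate(params, i, loc) <= 0)
        return(out("local_attractor", coex))
    }
  }

  # (b) basin probe: trajectories from the probe grid must all settle at the
  # coexistence equilibrium
  cp <- embed_two_species(params)
  for (a in controls$probe_grid) for (b in controls$probe_grid) {
    sim <- run_to_equilibrium(cp, c(a, b), controls$sim)
    if (!sim$converged) {
      inconclusive <- TRUE
      reason <- sprintf("probe from (%g, %g) did not converge", a, b)
      return(out("local_attractor", coex))
    }
    if (max(abs(sim$state - coex$location)) > controls$probe_dist)
      return(out("local_attractor", coex))
  }
  out("global_attractor", coex)
}

#' @export
print.coexistence_class <- function(x, ...) {
  cat(sprintf("<coexistence_class> %s%s\n", x$label,
              if (x$inconclusive) sprintf(" [inconclusive: %s]", x$reason)
              else ""))
  if (!is.null(x$coexistence_eq))
    cat(sprintf("  coexistence equilibrium: (%s), max Re(eig) = %.3g\n",
                paste(signif(x$coexistence_eq$location, 6), collapse = ", "),
                max(x$coexistence_eq$eig_real_parts)))
  invisible(x)
}
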