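# Seeded generation of random species pools for the four multispecies
# scenarios. Parameters are drawn from uniform distributions; all bounds are
# configurable because the reference analyses themselves vary them.

.pool_scenarios <- c("asym_competition_only", "repro_interference_only",
                     "basal_mortality_only", "all_asymmetries")

#' Species-pool distribution configuration
#'
#' Describes how random communities are drawn for the four scenarios:
#' \enumerate{
#'   \item only asymmetric competition (`comp` off-diagonals drawn),
#'   \item only asymmetric reproductive interference (`ri` drawn; competition
#'     symmetric at `symmetric_alpha`, default 0),
#'   \item only differences in basal mortality (`delta` drawn; competition
#'     symmetric at `symmetric_alpha`, default 0.05),
#'   \item all forms of asymmetry (everything drawn).
#' }
#' Default off-diagonal ranges are `U(0, 2/N)` so the expected total
#' interspecific pressure on a species is of the same order as its
#' self-limitation, keeping richness outcomes informative.
#'
#' @param scenario scenario name or index 1-4.
#' @param n_species species count N per pool.
#' @param comp_range,ri_range,delta_range uniform bounds (length-2, within
#'   \[0, 1\], low <= high) for the drawn off-diagonal entries.
#' @param symmetric_alpha fixed symmetric competition coefficient for
#'   scenarios 2-3; defaults to 0 (scenario 2) or 0.05 (scenario 3).
#' @param d minimum basal mortality rate.
#' @param pdd_fraction fraction of species undergoing density-dependent
#'   mortality; the remainder get the density-independent control kind
#'   (seeded draw). Default 1.
#' @param mortality_kind mortality kind for species undergoing density
#'   dependence.
#' @param seed master seed; pool k uses a counter-based child seed.
#' @return an object of class `pool_config`.
#' @examples
#' cfg <- pool_config(3, n_species = 30, seed = 1)
#' pool <- generate_pool(cfg, 1)
#' @export
pool_config <- function(scenario, n_species = 100,
                        comp_range = c(0, 2 / n_species),
                        ri_range = c(0, 2 / n_species),
                        delta_range = c(0, 1),
                        symmetric_alpha = NULL,
                        d = 0.5, pdd_fraction = 1,
                        mortality_kind = "hyperbolic", seed = 1) {
  if (is.numeric(scenario)) scenario <- .pool_scenarios[scenario]
  scenario <- match.arg(scenario, .pool_scenarios)
  check_range <- function(r, name) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0 || r[2] > 1)
      stop(sprintf("`%s` must be bounds low <= high within [0, 1]", name),
           call. = FALSE)
    as.numeric(r)
  }
  if (is.null(symmetric_alpha))
    symmetric_alpha <- switch(scenario, repro_interference_only = 0,
                              basal_mortality_only = 0.05, 0)
  stopifnot(n_species >= 1, pdd_fraction >= 0, pdd_fraction <= 1)
  structure(list(
    scenario = scenario, n_species = as.integer(n_species),
    comp_range = check_range(comp_range, "comp_range"),
    ri_range = check_range(ri_range, "ri_range"),
    delta_range = check_range(delta_range, "delta_range"),
    symmetric_alpha = check_unit_interval(symmetric_alpha, "symmetric_alpha"),
    d = check_unit_interval(d, "d"),
    pdd_fraction = pdd_fraction,
    mortality_kind = match.arg(mortality_kind, mortality_kinds()),
    seed = as.integer(seed)), class = "pool_config")
}

#' Generate one random species pool
#'
#' Draws a [community_params()] under the scenario mask of `config`.
#' Diagonals are exactly 1; off-diagonal entries are independent uniform
#' draws from the configured ranges (or fixed constants where the scenario
#' says so). Identical `(seed, pool_id)` gives a bitwise-identical pool.
#'
#' @param config a [pool_config()].
#' @param pool_id pool counter used to derive the child seed.
#' @param s density-dependence factor applied to every species (can be
#'   changed later with the experiment functions). Default 0.
#' @return a [community_params()] with attributes `pool_id` and `child_seed`.
#' @export
generate_pool <- function(config, pool_id = 1L, s = 0) {
  stopifnot(inherits(config, "pool_config"))
  N <- config$n_species
  child <- derive_seed(config$seed, pool_id)
  off <- which(row(diag(N)) != col(diag(N)))
  draws <- with_seed(child, {
    list(comp = runif(length(off), config$comp_range[1], config$comp_range[2]),
         ri = runif(length(off), config$ri_range[1], config$ri_range[2]),
         delta = runif(N, config$delta_range[1], config$delta_range[2]),
         pdd = sample.int(N, round(config$pdd_fraction * N)))
  })
  comp <- diag(1, N); ri <- diag(1, N); delta <- numeric(N)
  sc <- config$scenario
  if (sc %in% c("asym_competition_only", "all_asymmetries")) {
    comp[off] <- draws$comp
  } else {
    comp[off] <- config$symmetric_alpha
  }
  if (sc %in% c("repro_interference_only", "all_asymmetries"))
    ri[off] <- draws$ri
  if (sc %in% c("basal_mortality_only", "all_asymmetries"))
    delta <- draws$delta
  kinds <- rep("density-independent-control", N)
  kinds[draws$pdd] <- config$mortality_kind
  mort <- lapply(kinds, function(k) mortality_spec(k, s))
  params <- community_params(comp = comp, ri = ri, delta = delta,
                             d = config$d, mortality = mort)
  attr(params, "pool_id") <- pool_id
  attr(params, "child_seed") <- child
  params
}
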