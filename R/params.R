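# Parameter containers for the two-species and N-species models.
#
# Matrix convention throughout: `comp[i, j]` is the competition coefficient
# a_{j,i}, the per-capita effect of species j on species i, so the
# competitive pressure on species i is `(comp %*% n)[i]`. The same holds for
# the reproductive-interference matrix `ri`. Rows are the affected species;
# this is also the CSV layout used by the interface module.

.two_species_models <- c("asym_competition", "basal_mortality",
                         "repro_interference")

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

#' Two-species model parameters
#'
#' The three two-species systems share a logistic core plus a
#' density-dependent mortality term `d * D(n_i)` and differ in the form of
#' asymmetry between species:
#' \describe{
#'   \item{`asym_competition`}{species 1 depresses species 2 with intensity
#'     `alpha1` while species 2 has no effect on species 1.}
#'   \item{`basal_mortality`}{symmetric competition `alpha`; species 2 pays
#'     an extra basal mortality, `d + delta * (1 - d)`.}
#'   \item{`repro_interference`}{symmetric competition `alpha`; the growth
#'     term of species 2 is reduced by the frequency-dependent factor
#'     `1 / (1 + alpha1p * n1 / n2)`.}
#' }
#' Parameters that do not belong to `model` must be left at 0.
#'
#' @param model one of `"asym_competition"`, `"basal_mortality"`,
#'   `"repro_interference"`.
#' @param d basal mortality rate relative to the growth rate, in \[0, 1\].
#' @param alpha1 asymmetric competition intensity in \[0, 1\].
#' @param alpha symmetric competition intensity in \[0, 1\].
#' @param delta basal-mortality difference in \[0, 1\].
#' @param alpha1p asymmetric reproductive-interference intensity in \[0, 1\].
#' @param mortality a [mortality_spec()].
#' @return an object of class `two_species_params`.
#' @examples
#' p <- two_species_params("asym_competition", d = 0.5, alpha1 = 0.5)
#' evaluate_rhs(p, c(0.5, 0.25))
#' @export
two_species_params <- function(model, d, alpha1 = 0, alpha = 0, delta = 0,
                               alpha1p = 0, mortality = mortality_spec()) {
  model <- match.arg(model, .two_species_models)
  d <- check_unit_interval(d, "d")
  alpha1 <- check_unit_interval(alpha1, "alpha1")
  alpha <- check_unit_interval(alpha, "alpha")
  delta <- check_unit_interval(delta, "delta")
  alpha1p <- check_unit_interval(alpha1p, "alpha1p")
  stopifnot(is_mortality_spec(mortality))
  used <- switch(model,
    asym_competition = "alpha1",
    basal_mortality = c("alpha", "delta"),
    repro_interference = c("alpha", "alpha1p"))
  vals <- c(alpha1 = alpha1, alpha = alpha, delta = delta, alpha1p = alpha1p)
  off <- setdiff(names(vals), used)
  if (any(vals[off] != 0))
    stop(sprintf("parameters not used by model '%s' must be 0: %s", model,
                 paste(off[vals[off] != 0], collapse = ", ")), call. = FALSE)
  structure(list(model = model, d = d, alpha1 = alpha1, alpha = alpha,
                 delta = delta, alpha1p = alpha1p, mortality = mortality),
            class = "two_species_params")
}

#' @export
print.two_species_params <- function(x, ...) {
  cat(sprintf("<two_species_params> %s d=%g alpha1=%g alpha=%g delta=%g alpha1p=%g (%s, s=%g)\n",
              x$model, x$d, x$alpha1, x$alpha, x$delta, x$alpha1p,
              x$mortality$kind, x$mortality$s))
  invisible(x)
}

# Canonical per-species mortality table: kind codes (for the C++ core),
# kind names, s and reference densities, one entry per species.
as_mortality_table <- function(mortality, n_species) {
  specs <- if (is_mortality_spec(mortality)) {
    rep(list(mortality), n_species)
  } else if (is.list(mortality) && length(mortality) == n_species &&
             all(vapply(mortality, is_mortality_spec, logical(1)))) {
    mortality
  } else {
    stop("`mortality` must be a mortality_spec or a list of one per species",
         call. = FALSE)
  }
  kind <- vapply(specs, function(x) x$kind, character(1))
  code <- .builtin_mortality_codes[kind]
  list(kind = kind,
       code = unname(code),                 # NA for non-builtin kinds
       s = vapply(specs, function(x) x$s, numeric(1)),
       ref = vapply(specs, function(x) x$ref_density, numeric(1)),
       specs = specs)
}

#' N-species community parameters
#'
#' Generalizes the two-species systems to N species: each species i grows
#' with a frequency-dependent term `1 / (sum_j ri[i,j] n_j / n_i)`, is
#' depressed by competition `sum_j comp[i,j] n_j`, and dies at rate
#' `(d + delta[i] (1 - d)) * D(n_i)`. Diagonals of both matrices must be
#' exactly 1 (conspecific interactions are the reference).
#'
#' @param comp N x N competition matrix; `comp[i, j]` is the effect of
#'   species j on species i, in \[0, 1\], diagonal 1.
#' @param ri N x N reproductive-interference matrix, same convention;
#'   defaults to the identity pattern (no interference).
#' @param delta length-N vector of basal-mortality increments in \[0, 1\];
#'   defaults to 0.
#' @param d minimum basal mortality rate in \[0, 1\].
#' @param mortality a [mortality_spec()], or a list of one per species
#'   (used e.g. when only a fraction of species undergo density-dependent
#'   mortality).
#' @return an object of class `community_params`.
#' @export
community_params <- function(comp, ri = NULL, delta = NULL, d,
                             mortality = mortality_spec()) {
  comp <- as.matrix(comp)
  N <- nrow(comp)
  if (ncol(comp) != N) stop("`comp` must be square", call. = FALSE)
  if (is.null(ri)) {
    ri <- diag(1, N)
  } else {
    ri <- as.matrix(ri)
    if (!all(dim(ri) == c(N, N))) stop("`ri` must be N x N", call. = FALSE)
  }
  if (is.null(delta)) delta <- numeric(N)
  if (length(delta) != N) stop("`delta` must have one entry per species",
                               call. = FALSE)
  check_unit_interval(comp, "comp")
  check_unit_interval(ri, "ri")
  delta <- check_unit_interval(delta, "delta")
  d <- check_unit_interval(d, "d")
  if (any(diag(comp) != 1) || any(diag(ri) != 1))
    stop("diagonals of `comp` and `ri` must be exactly 1", call. = FALSE)
  mt <- as_mortality_table(mortality, N)
  structure(list(N = N, comp = comp, ri = ri, delta = delta, d = d,
                 mortality = mt),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat(sprintf("<community_params> N=%d d=%g mortality=%s s in [%g, %g]\n",
              x$N, x$d, paste(unique(x$mortality$kind), collapse = "/"),
              min(x$mortality$s), max(x$mortality$s)))
  invisible(x)
}

#' Embed a two-species model in the N-species form
#'
#' Returns an `N = 2` [community_params()] whose right-hand side agrees with
#' the corresponding two-species system at machine precision for all states.
#'
#' @param params a [two_species_params()].
#' @return a [community_params()] with `N = 2`.
#' @export
embed_two_species <- function(params) {
  stopifnot(inherits(params, "two_species_params"))
  comp <- switch(params$model,
    asym_competition = matrix(c(1, params$alpha1, 0, 1), 2, 2),
    matrix(c(1, params$alpha, params$alpha, 1), 2, 2))
  ri <- diag(1, 2)
  if (params$model == "repro_interference") ri[2, 1] <- params$alpha1p
  delta <- c(0, if (params$model == "basal_mortality") params$delta else 0)
  community_params(comp = comp, ri = ri, delta = delta, d = params$d,
                   mortality = params$mortality)
}

# Restrict a community to the species in `idx` (used for stability checks of
# surviving subcommunities).
subset_community <- function(params, idx) {
  stopifnot(inherits(params, "community_params"))
  community_params(comp = params$comp[idx, idx, drop = FALSE],
                   ri = params$ri[idx, idx, drop = FALSE],
                   delta = params$delta[idx], d = params$d,
                   mortality = params$mortality$specs[idx])
}

# Replace the density-dependence factor s for every species (richness scans
# vary s with everything else held fixed).
set_density_dependence <- function(params, s) {
  stopifnot(inherits(params, "community_params"))
  params$mortality$s <- rep(as.numeric(s), params$N)
  params$mortality$specs <- lapply(seq_len(params$N), function(i)
    mortality_spec(params$mortality$kind[i], s, params$mortality$ref[i]))
  params
}
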