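# Parameter-plane sweeps over (asymmetry parameter, s) producing tristate
# coexistence maps and equilibrium-density surfaces, and numerical
# extraction of the s values at which the classification changes.

.asymmetry_param <- c(asym_competition = "alpha1", basal_mortality = "delta",
                      repro_interference = "alpha1p")

# Build the two-species params for one scan cell.
cell_params <- function(model_kind, x_value, s, fixed) {
  args <- list(model = model_kind,
               d = if (is.null(fixed$d)) 0.5 else fixed$d,
               mortality = mortality_spec(
                 if (is.null(fixed$mortality_kind)) "hyperbolic"
                 else fixed$mortality_kind, s))
  if (model_kind != "asym_competition")
    args$alpha <- if (is.null(fixed$alpha)) 0 else fixed$alpha
  args[[.asymmetry_param[[model_kind]]]] <- x_value
  do.call(two_species_params, args)
}

#' Canonical density-dependence grid
#'
#' `{0}` plus `n` log-spaced points spanning `range`. The default spans
#' `[1e-2, 1e4]`; positive density dependence acts at all densities only for
#' `s <= 100`, so maps are conventionally split at `s = 100` when displayed.
#'
#' @param n number of positive grid points (default 60).
#' @param range range of the positive part (default `c(1e-2, 1e4)`).
#' @export
canonical_s_grid <- function(n = 60, range = c(1e-2, 1e4)) {
  c(0, 10^seq(log10(range[1]), log10(range[2]), length.out = n))
}

#' Scan a (asymmetry, s) parameter plane
#'
#' Classifies every grid cell with [classify_coexistence()] and records the
#' interior equilibrium densities where coexistence exists. Inconclusive
#' cells are recorded as such, never interpolated.
#'
#' @param model_kind one of the two-species model names.
#' @param x_grid grid of the asymmetry parameter (`alpha1`, `delta` or
#'   `alpha1p` depending on the model).
#' @param s_grid grid of density-dependence factors, e.g.
#'   [canonical_s_grid()].
#' @param fixed_params named list of the remaining parameters (`d`, `alpha`,
#'   `mortality_kind`).
#' @param controls a [classify_controls()] list.
#' @return an object of class `scan_result`: grids, a `classes` character
#'   matrix (`|x_grid|` rows by `|s_grid|` columns), matrices `n1_star` /
#'   `n2_star` (NA where there is no coexistence equilibrium), a logical
#'   `inconclusive` matrix, and the fixed parameters.
#' @export
scan_plane <- function(model_kind, x_grid, s_grid, fixed_params = list(),
                       controls = classify_controls()) {
  model_kind <- match.arg(model_kind, .two_species_models)
  stopifnot(length(x_grid) >= 1, length(s_grid) >= 1)
  nx <- length(x_grid); ns <- length(s_grid)
  classes <- matrix(NA_character_, nx, ns)
  n1s <- matrix(NA_real_, nx, ns)
  n2s <- matrix(NA_real_, nx, ns)
  inc <- matrix(FALSE, nx, ns)
  for (i in seq_len(nx)) for (j in seq_len(ns)) {
    cl <- classify_coexistence(
      cell_params(model_kind, x_grid[i], s_grid[j], fixed_params), controls)
    classes[i, j] <- cl$label
    inc[i, j] <- cl$inconclusive
    if (!is.null(cl$coexistence_eq)) {
      n1s[i, j] <- cl$coexistence_eq$location[1]
      n2s[i, j] <- cl$coexistence_eq$location[2]
    }
  }
  structure(list(model_kind = model_kind,
                 x_name = .asymmetry_param[[model_kind]],
                 x_grid = x_grid, s_grid = s_grid, classes = classes,
                 n1_star = n1s, n2_star = n2s, inconclusive = inc,
                 fixed = fixed_params),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s: %d x-values (%s) x %d s-values\n",
              x$model_kind, length(x$x_grid), x$x_name, length(x$s_grid)))
  print(table(classes = x$classes))
  invisible(x)
}

# Flatten a scan to the CSV record layout.
#' @export
as.data.frame.scan_result <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$x_grid), j = seq_along(x$s_grid))
  data.frame(x_name = x$x_name,
             x_value = x$x_grid[grid$i],
             s = x$s_grid[grid$j],
             class = x$classes[cbind(grid$i, grid$j)],
             n1_star = x$n1_star[cbind(grid$i, grid$j)],
             n2_star = x$n2_star[cbind(grid$i, grid$j)],
             inconclusive_flag = x$inconclusive[cbind(grid$i, grid$j)])
}

#' Locate the s values where the coexistence class changes
#'
#' Classifies along `s_grid` at a fixed asymmetry value and bisects every
#' class change in log10(s) to relative tolerance `log_tol`, returning the
#' ordered transition points with the class on each side. A change between
#' `s = 0` and the first positive grid point is bisected down to `s = 1e-8`.
#'
#' @inheritParams scan_plane
#' @param x_value the fixed asymmetry parameter value.
#' @param log_tol bisection tolerance in log10(s) (default `1e-3`).
#' @return data frame with columns `s`, `from`, `to` (empty if the class
#'   never changes).
#' @export
find_s_threshold <- function(model_kind, fixed_params, x_value,
                             s_grid = canonical_s_grid(), log_tol = 1e-3,
                             controls = classify_controls()) {
  model_kind <- match.arg(model_kind, .two_species_models)
  lab <- function(s) {
    cl <- classify_coexistence(cell_params(model_kind, x_value, s,
                                           fixed_params), controls)
    if (cl$inconclusive)
      stop(sprintf("classification inconclusive at s=%g: %s", s, cl$reason),
           call. = FALSE)
    cl$label
  }
  labs <- vapply(s_grid, lab, character(1))
  out <- list()
  for (k in seq_len(length(s_grid) - 1L)) {
    if (labs[k] == labs[k + 1L]) next
    lo <- if (s_grid[k] > 0) log10(s_grid[k]) else -8
    hi <- log10(s_grid[k + 1L])
    lab_lo <- labs[k]
    while (hi - lo > log_tol) {
      mid <- (lo + hi) / 2
      if (lab(10^mid) == lab_lo) lo <- mid else hi <- mid
    }
    out[[length(out) + 1L]] <- data.frame(s = 10^((lo + hi) / 2),
                                          from = labs[k], to = labs[k + 1L])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(s = numeric(0), from = character(0), to = character(0))
}
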