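# Density-dependent mortality multipliers D(n).
#
# Mortality enters the models as d * D(n): a basal rate d scaled by a
# multiplier D that declines with conspecific density n. The canonical form
# is hyperbolic, D(n) = 1 / (1 + s n), whose decline rate at zero density is
# exactly s (D'(0) = -s). Alternative forms live in a registry keyed by
# `kind` so that new mortality functions can be added without touching the
# rest of the package.

.mortality_registry <- new.env(parent = emptyenv())

#' Register a mortality kind
#'
#' Adds (or replaces) a density-dependent mortality multiplier in the
#' package registry. Each kind is a family of functions of density `n`
#' indexed by the density-dependence factor `s` (and, for
#' density-independent controls, a reference density `ref`). Every kind must
#' map into \[0, 1\] for all `n >= 0`, `s >= 0`, and must reduce to the
#' constant 1 when `s = 0`.
#'
#' @param kind character scalar naming the family.
#' @param D function(n, s, ref) returning the multiplier.
#' @param dDdn function(n, s, ref) returning the density slope dD/dn, or
#'   `NULL` to fall back on a central finite difference.
#' @param dDds function(n, s, ref) returning the factor sensitivity dD/ds,
#'   or `NULL` to fall back on a central finite difference.
#' @return `kind`, invisibly.
#' @export
register_mortality_kind <- function(kind, D, dDdn = NULL, dDds = NULL) {
  stopifnot(is.character(kind), length(kind) == 1L, is.function(D))
  assign(kind, list(D = D, dDdn = dDdn, dDds = dDds),
         envir = .mortality_registry)
  invisible(kind)
}

mortality_kinds <- function() ls(.mortality_registry)

# Builtin kinds. Codes in parentheses are the integer ids used by the C++
# integrator (see src/integrate.cpp); keep the two in sync.
.builtin_mortality_codes <- c(
  hyperbolic = 0L, exponential = 1L, linear = 2L,
  "density-independent-control" = 3L
)

.init_mortality_registry <- function() {
  register_mortality_kind(
    "hyperbolic",
    D    = function(n, s, ref) 1 / (1 + s * n),
    dDdn = function(n, s, ref) -s / (1 + s * n)^2,
    dDds = function(n, s, ref) -n / (1 + s * n)^2
  )
  register_mortality_kind(
    "exponential",
    D    = function(n, s, ref) exp(-s * n),
    dDdn = function(n, s, ref) -s * exp(-s * n),
    dDds = function(n, s, ref) -n * exp(-s * n)
  )
  register_mortality_kind(
    "linear",
    D    = function(n, s, ref) pmax(0, 1 - s * n),
    dDdn = function(n, s, ref) ifelse(s * n < 1, -s, 0),
    dDds = function(n, s, ref) ifelse(s * n < 1, -n, 0)
  )
  # Control without density dependence: the multiplier is held at its value
  # at a fixed reference density, so increased s still reduces mortality but
  # density feedback is switched off.
  register_mortality_kind(
    "density-independent-control",
    D    = function(n, s, ref) 1 / (1 + s * ref) + 0 * n,
    dDdn = function(n, s, ref) 0 * n,
    dDds = function(n, s, ref) -ref / (1 + s * ref)^2 + 0 * n
  )
}
.init_mortality_registry()

#' Density-dependent mortality specification
#'
#' @param kind one of `"hyperbolic"` (default, `D(n) = 1/(1+sn)`),
#'   `"exponential"` (`exp(-sn)`), `"linear"` (`max(0, 1-sn)`) or
#'   `"density-independent-control"` (constant `1/(1+s*ref_density)`), or
#'   any kind added via [register_mortality_kind()].
#' @param s nonnegative density-dependence factor: the decline rate of the
#'   multiplier at zero density (`D'(0) = -s` for the density-dependent
#'   kinds). `s = 0` gives constant mortality for every kind.
#' @param ref_density reference density for the density-independent control.
#' @return an object of class `mortality_spec`.
#' @examples
#' sp <- mortality_spec("hyperbolic", s = 1)
#' evaluate_mortality(sp, c(0, 1, 10))
#' @export
mortality_spec <- function(kind = "hyperbolic", s = 0, ref_density = 1) {
  kind <- match.arg(kind, mortality_kinds())
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
    stop("`s` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(ref_density) || length(ref_density) != 1L || ref_density <= 0)
    stop("`ref_density` must be a single positive number", call. = FALSE)
  structure(list(kind = kind, s = as.numeric(s),
                 ref_density = as.numeric(ref_density)),
            class = "mortality_spec")
}

is_mortality_spec <- function(x) inherits(x, "mortality_spec")

check_mortality_args <- function(spec, n) {
  if (!is_mortality_spec(spec)) stop("`spec` must be a mortality_spec",
                                     call. = FALSE)
  if (!is.numeric(n) || anyNA(n) || any(n < 0))
    stop("densities must be nonnegative", call. = FALSE)
}

#' @export
print.mortality_spec <- function(x, ...) {
  cat(sprintf("<mortality_spec> kind=%s s=%g\n", x$kind, x$s))
  invisible(x)
}

#' Evaluate the mortality multiplier D(n)
#'
#' @param spec a [mortality_spec()].
#' @param n vector of nonnegative densities.
#' @return multipliers in \[0, 1\], one per density.
#' @export
evaluate_mortality <- function(spec, n) {
  check_mortality_args(spec, n)
  entry <- get(spec$kind, envir = .mortality_registry)
  entry$D(n, spec$s, spec$ref_density)
}

#' Slope of the mortality multiplier in density, dD/dn
#'
#' For the hyperbolic kind this is `-s/(1+sn)^2`; at `n = 0` the
#' density-dependent kinds are normalized so the slope equals `-s`.
#'
#' @inheritParams evaluate_mortality
#' @export
mortality_density_slope <- function(spec, n) {
  check_mortality_args(spec, n)
  entry <- get(spec$kind, envir = .mortality_registry)
  if (!is.null(entry$dDdn)) return(entry$dDdn(n, spec$s, spec$ref_density))
  h <- 1e-6 * pmax(1, abs(n))
  (entry$D(n + h, spec$s, spec$ref_density) -
     entry$D(pmax(n - h, 0), spec$s, spec$ref_density)) / (n + h - pmax(n - h, 0))
}

#' Sensitivity of the mortality multiplier to the factor s, dD/ds
#'
#' For the hyperbolic kind this is `-n/(1+sn)^2`: nonpositive everywhere,
#' zero at `n = 0`, and vanishing again at high density. The vanishing tail
#' is the key nonlinearity of the model: raising `s` barely reduces the
#' mortality of an abundant species while greatly reducing that of a rare
#' one.
#'
#' @inheritParams evaluate_mortality
#' @export
mortality_factor_sensitivity <- function(spec, n) {
  check_mortality_args(spec, n)
  entry <- get(spec$kind, envir = .mortality_registry)
  if (!is.null(entry$dDds)) return(entry$dDds(n, spec$s, spec$ref_density))
  h <- 1e-6 * max(1, spec$s)
  up <- mortality_spec(spec$kind, spec$s + h, spec$ref_density)
  dn <- mortality_spec(spec$kind, max(spec$s - h, 0), spec$ref_density)
  (evaluate_mortality(up, n) - evaluate_mortality(dn, n)) /
    (spec$s + h - max(spec$s - h, 0))
}
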