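# Right-hand sides of the dynamical systems.
#
# The reproductive-interference growth term printed as
#   1 / (1 + a' n1 / n2)
# is evaluated in the singularity-free form n_i^2 / (sum_j ri[i,j] n_j),
# which is algebraically identical for n_i > 0 (the diagonal of `ri` is 1)
# and equal to 0 at n_i = 0, so extinction is an absorbing state of the flow.

#' Evaluate the model right-hand side dn/dt
#'
#' @param params a [two_species_params()] or [community_params()].
#' @param n vector of nonnegative densities (length 2 or N).
#' @return vector of per-unit-time density changes, one per species. Any
#'   species at density 0 has derivative exactly 0.
#' @export
evaluate_rhs <- function(params, n) UseMethod("evaluate_rhs")

check_state <- function(n, len) {
  if (!is.numeric(n) || anyNA(n))
    stop("state must be numeric and free of NA", call. = FALSE)
  if (length(n) != len)
    stop(sprintf("state must have length %d", len), call. = FALSE)
  if (any(n < 0)) stop("densities must be nonnegative", call. = FALSE)
}

#' @export
evaluate_rhs.two_species_params <- function(params, n) {
  check_state(n, 2L)
  n1 <- n[1]; n2 <- n[2]
  d <- params$d
  D <- function(x) evaluate_mortality(params$mortality, x)
  switch(params$model,
    asym_competition = c(
      n1 * (1 - n1 - d * D(n1)),
      n2 * (1 - n2 - params$alpha1 * n1 - d * D(n2))),
    basal_mortality = c(
      n1 * (1 - n1 - params$alpha * n2 - d * D(n1)),
      n2 * (1 - n2 - params$alpha * n1 -
              (d + params$delta * (1 - d)) * D(n2))),
    repro_interference = {
      growth2 <- if (n2 > 0) n2^2 / (params$alpha1p * n1 + n2) else 0
      c(n1 * (1 - n1 - params$alpha * n2 - d * D(n1)),
        growth2 - n2 * (n2 + params$alpha * n1 + d * D(n2)))
    })
}

#' @export
evaluate_rhs.community_params <- function(params, n) {
  check_state(n, params$N)
  rhs_community_r(params, n)
}

# Pure-R community right-hand side; the reference implementation against
# which the C++ core used by the integrator is tested.
rhs_community_r <- function(params, n) {
  cn <- drop(params$comp %*% n)
  rn <- drop(params$ri %*% n)
  m <- params$d + params$delta * (1 - params$d)
  D <- vapply(seq_len(params$N), function(i)
    evaluate_mortality(params$mortality$specs[[i]], n[i]), numeric(1))
  growth <- ifelse(n > 0, n^2 / rn, 0)
  out <- growth - n * (cn + m * D)
  out[n == 0] <- 0
  out
}

# C++ community right-hand side (builtin mortality kinds only).
rhs_community_fast <- function(params, n) {
  rhs_community_cpp(params$comp, params$ri, params$delta, params$d,
                    params$mortality$code, params$mortality$s,
                    params$mortality$ref, n)
}
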