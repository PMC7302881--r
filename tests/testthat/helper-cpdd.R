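# Shared fixtures: random parameter draws used by the property-style tests.

random_two_species <- function(model, s = NULL) {
  if (is.null(s)) s <- 10^runif(1, -2, 4)
  switch(model,
    asym_competition = two_species_params(
      "asym_competition", d = runif(1, 0, 0.95), alpha1 = runif(1),
      mortality = mortality_spec("hyperbolic", s)),
    basal_mortality = two_species_params(
      "basal_mortality", d = runif(1, 0, 0.95), alpha = runif(1),
      delta = runif(1), mortality = mortality_spec("hyperbolic", s)),
    repro_interference = two_species_params(
      "repro_interference", d = runif(1, 0, 0.95), alpha = runif(1),
      alpha1p = runif(1), mortality = mortality_spec("hyperbolic", s)))
}

random_community <- function(N = 5, s = NULL) {
  if (is.null(s)) s <- 10^runif(1, -2, 4)
  off <- which(row(diag(N)) != col(diag(N)))
  comp <- diag(1, N); comp[off] <- runif(length(off), 0, 2 / N)
  ri <- diag(1, N); ri[off] <- runif(length(off), 0, 2 / N)
  community_params(comp = comp, ri = ri, delta = runif(N), d = runif(1),
                   mortality = mortality_spec("hyperbolic", s))
}

two_species_models <- c("asym_competition", "basal_mortality",
                        "repro_interference")
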