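# Shared fixtures: the two inactivation scenarios used throughout, and a
# deterministic generator of random parameter sets for property tests.

paternal_scenario <- function() {
  list(locus = imprinting_locus(a = 1/2, k1 = 9/10, k2 = -8/10),
       pop = population_state(p1 = 1/2))
}

maternal_scenario <- function() {
  list(locus = imprinting_locus(a = 1/2, k1 = -7/10, k2 = 95/100),
       pop = population_state(p1 = 1/3))
}

# random locus/population/selection draws with admissible fitnesses
draw_parameters <- function(inbred = FALSE) {
  a <- runif(1, -1.5, 1.5)
  locus <- imprinting_locus(a, runif(1, -1, 1), runif(1, -1, 1))
  pop <- population_state(runif(1, 0.05, 0.95), if (inbred) runif(1) else 0)
  t <- runif(1, -0.45, 0.45) / max(abs(genotypic_values(locus)), 0.25)
  list(locus = locus, pop = pop, sel = selection_model(t))
}

expect_printed <- function(actual, printed, digits = 4) {
  # agreement with a value printed to `digits` decimals: within half a unit
  # in the last printed place
  expect_true(all(abs(actual - printed) <= 0.5 * 10^(-digits) + 1e-12),
              label = paste0(deparse(substitute(actual)), " = ",
                             paste(format(actual), collapse = ", "),
                             " vs printed ",
                             paste(format(printed), collapse = ", ")))
}
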