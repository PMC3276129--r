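#' @keywords internal
"_PACKAGE"

# Genotypes are ordered (maternal allele, paternal allele) pairs throughout:
# A2A1 carries a maternally inherited A2, A1A2 a paternally inherited A2.
# The two reciprocal heterozygotes are never merged.
GENOTYPES <- c("A1A1", "A2A1", "A1A2", "A2A2")
GENO_MAT <- c(1L, 2L, 1L, 2L)
GENO_PAT <- c(1L, 1L, 2L, 2L)

#' Imprinted diallelic locus
#'
#' Defines the genotypic-value scale of a one-locus, two-allele quantitative
#' trait subject to genomic imprinting. On this scale the \code{A1A1}
#' homozygote has value 0 and the \code{A2A2} homozygote \code{2a}. The two
#' reciprocal heterozygotes may differ: a maternally inherited A2 gives value
#' \code{a(1+k1)}, a paternally inherited A2 gives \code{a(1+k2)}.
#'
#' \code{k1 = k2 = 0} is pure additivity; \code{k1 = k2 = k != 0} is ordinary
#' dominance with Mendelian expression; \code{k1 = -k2} is imprinting without
#' dominance (the heterozygote mean sits midway between the homozygotes);
#' \code{k1 = 1, k2 = -1} is complete silencing of the paternal allele and
#' \code{k1 = -1, k2 = 1} complete silencing of the maternal allele.
#'
#' @param a trait-scale parameter; half the homozygote difference. Finite scalar.
#' @param k1 imprinting/dominance coefficient of the maternal-A2 heterozygote,
#'   in \code{[-1, 1]}.
#' @param k2 imprinting/dominance coefficient of the paternal-A2 heterozygote,
#'   in \code{[-1, 1]}.
#' @return An object of class \code{"imprinting_locus"}.
#' @examples
#' loc <- imprinting_locus(a = 1/2, k1 = 9/10, k2 = -8/10)
#' genotypic_values(loc)
#' @seealso [genotypic_values()], [population_state()]
#' @export
imprinting_locus <- function(a, k1, k2) {
  check_scalar(a, "a")
  check_scalar(k1, "k1")
  check_scalar(k2, "k2")
  if (k1 < -1 || k1 > 1) stop("'k1' must lie in [-1, 1], got ", k1, call. = FALSE)
  if (k2 < -1 || k2 > 1) stop("'k2' must lie in [-1, 1], got ", k2, call. = FALSE)
  structure(list(a = a, k1 = k1, k2 = k2), class = "imprinting_locus")
}

#' Population state: allele frequency and inbreeding coefficient
#'
#' The population is described by the frequency \code{p1} of allele A1
#' (\code{p2 = 1 - p1}) and an inbreeding coefficient \code{f}, modelled as a
#' mixture: a fraction \code{1 - f} of the population in Hardy-Weinberg
#' proportions and a fraction \code{f} fully homozygous. \code{f} is treated
#' as stable across generations.
#'
#' @param p1 frequency of allele A1, in \code{[0, 1]}.
#' @param f inbreeding coefficient, in \code{[0, 1]}. Default 0 (random mating).
#' @return An object of class \code{"population_state"}.
#' @examples
#' population_state(p1 = 1/2)
#' genotype_frequencies(population_state(1/3, f = 1/4))
#' @export
population_state <- function(p1, f = 0) {
  check_scalar(p1, "p1")
  check_scalar(f, "f")
  if (p1 < 0 || p1 > 1) stop("'p1' must lie in [0, 1], got ", p1, call. = FALSE)
  if (f < 0 || f > 1) stop("'f' must lie in [0, 1], got ", f, call. = FALSE)
  if (p1 == 0 || p1 == 1)
    warning("population is monomorphic (p1 = ", p1, "); all genetic variances are 0")
  structure(list(p1 = p1, p2 = 1 - p1, f = f), class = "population_state")
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  invisible(x)
}

require_outbred <- function(pop, fun) {
  if (pop$f != 0)
    stop(fun, "() is defined for f = 0; use the inbreeding functions ",
         "(mean_inbred, inbred_variance_components) for f > 0", call. = FALSE)
  invisible(pop)
}

#' @export
print.imprinting_locus <- function(x, ...) {
  cat("Imprinted diallelic locus\n")
  cat(sprintf("  a = %g, k1 = %g (maternal A2), k2 = %g (paternal A2)\n",
              x$a, x$k1, x$k2))
  g <- genotypic_values(x)
  cat("  genotypic values: ",
      paste(sprintf("%s = %g", names(g), g), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: p1 = %g, p2 = %g, f = %g\n", x$p1, x$p2, x$f))
  invisible(x)
}

#' Genotypic values of the four ordered genotypes
#'
#' @param locus an [imprinting_locus()].
#' @return Named numeric vector over \code{A1A1, A2A1, A1A2, A2A2} (maternal
#'   allele written first): \code{0, a(1+k1), a(1+k2), 2a}.
#' @export
genotypic_values <- function(locus) {
  stopifnot(inherits(locus, "imprinting_locus"))
  c(A1A1 = 0, A2A1 = locus$a * (1 + locus$k1),
    A1A2 = locus$a * (1 + locus$k2), A2A2 = 2 * locus$a)
}

#' Genotype frequencies under the inbreeding mixture
#'
#' Frequencies of the ordered genotypes: \code{p1^2 + f p1 p2} for A1A1,
#' \code{p1 p2 (1-f)} for each reciprocal heterozygote, and
#' \code{p2^2 + f p1 p2} for A2A2. At \code{f = 0} these are the
#' Hardy-Weinberg proportions.
#'
#' @param pop a [population_state()].
#' @return Named numeric vector over the four ordered genotypes, summing to 1.
#' @export
genotype_frequencies <- function(pop) {
  stopifnot(inherits(pop, "population_state"))
  p1 <- pop$p1; p2 <- pop$p2; f <- pop$f
  c(A1A1 = p1^2 + f * p1 * p2,
    A2A1 = p1 * p2 * (1 - f),
    A1A2 = p1 * p2 * (1 - f),
    A2A2 = p2^2 + f * p1 * p2)
}

#' Sex-specific average-effect terms
#'
#' The composite terms \code{alpha_f = a(1 + k1 p1 - k2 p2)} and
#' \code{alpha_m = a(1 + k2 p1 - k1 p2)} through which every maternal
#' (respectively paternal) additive quantity is expressed. They satisfy
#' \code{alpha_f - alpha_m = a(k1 - k2)} identically, and collapse to the
#' usual average effect \code{a(1 + k(p1 - p2))} when \code{k1 = k2 = k}.
#' The inbreeding coefficient is ignored here; inbred average effects are
#' computed by [inbred_additive_effects()].
#'
#' @inheritParams genotypic_values
#' @param pop a [population_state()].
#' @return Named numeric vector \code{c(alpha_f, alpha_m)}.
#' @export
alphas <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2; p1 <- pop$p1; p2 <- pop$p2
  c(alpha_f = a * (1 + k1 * p1 - k2 * p2),
    alpha_m = a * (1 + k2 * p1 - k1 * p2))
}

#' Population mean genotypic value (random mating)
#'
#' \code{mu = a p2 (2 + p1 (k1 + k2))}, the Hardy-Weinberg
#' frequency-weighted mean of the genotypic values. Requires \code{f = 0};
#' use [mean_inbred()] for an inbred population.
#'
#' @inheritParams alphas
#' @return Scalar mean on the trait scale.
#' @export
population_mean <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  require_outbred(pop, "population_mean")
  locus$a * pop$p2 * (2 + pop$p1 * (locus$k1 + locus$k2))
}

#' Total genetic variance (random mating)
#'
#' \code{sigma2_G = p1 p2 (alpha_f^2 + alpha_m^2 + a^2 p1 p2 (k1+k2)^2)},
#' identical across all decomposition approaches. Requires \code{f = 0};
#' use [total_variance_inbred()] for an inbred population.
#'
#' @inheritParams alphas
#' @return Scalar variance on the squared trait scale.
#' @export
total_genetic_variance <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  require_outbred(pop, "total_genetic_variance")
  al <- alphas(locus, pop)
  p1 <- pop$p1; p2 <- pop$p2
  p1 * p2 * (al[["alpha_f"]]^2 + al[["alpha_m"]]^2 +
               locus$a^2 * p1 * p2 * (locus$k1 + locus$k2)^2)
}
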