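# Exhaustive-enumeration oracle. Everything here is computed from first
# principles — genotype frequencies, Mendelian 1/2-1/2 gamete segregation,
# random mating, fitness weighting — without using any of the closed forms,
# so it serves as independent ground truth for the rest of the package.

# transmission matrix: T[g, allele] = P(genotype g transmits that allele)
transmission_matrix <- function() {
  cbind(((GENO_MAT == 1L) + (GENO_PAT == 1L)) / 2,
        ((GENO_MAT == 2L) + (GENO_PAT == 2L)) / 2)
}

# genotypic values as a 2x2 matrix indexed [maternal allele, paternal allele]
gvalue_matrix <- function(locus) {
  m <- matrix(0, 2, 2)
  m[2, 1] <- locus$a * (1 + locus$k1)
  m[1, 2] <- locus$a * (1 + locus$k2)
  m[2, 2] <- 2 * locus$a
  m
}

#' Exhaustive mating table
#'
#' The joint distribution over (mother genotype, father genotype, offspring
#' genotype) under random mating: parents are two independent draws from the
#' population's genotype distribution (the inbreeding mixture if
#' \code{f > 0}), gametes segregate 1/2-1/2, and the maternal gamete fills
#' the offspring's maternal slot. Probabilities sum to one and, with no
#' selection, the offspring allele frequency equals the parental one.
#'
#' @inheritParams alphas
#' @return Data frame with columns \code{mother}, \code{father},
#'   \code{offspring} (ordered genotype labels) and \code{prob}; 64 rows
#'   (many structurally zero).
#' @export
build_mating_table <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  fr <- genotype_frequencies(pop)
  TT <- transmission_matrix()
  grid <- expand.grid(mother = seq_len(4), father = seq_len(4),
                      offspring = seq_len(4))
  prob <- fr[grid$mother] * fr[grid$father] *
    TT[cbind(grid$mother, GENO_MAT[grid$offspring])] *
    TT[cbind(grid$father, GENO_PAT[grid$offspring])]
  data.frame(mother = GENOTYPES[grid$mother],
             father = GENOTYPES[grid$father],
             offspring = GENOTYPES[grid$offspring],
             prob = as.numeric(prob))
}

#' Oracle mean and variance of the genotypic value
#'
#' Frequency-weighted first and second moments over the genotype
#' distribution (including the inbreeding mixture); validates the closed
#' forms for the mean and total variance.
#'
#' @inheritParams alphas
#' @return Named numeric vector \code{c(mean, variance)}.
#' @export
oracle_moments <- function(locus, pop) {
  fr <- genotype_frequencies(pop)
  G <- genotypic_values(locus)
  mu <- sum(fr * G)
  c(mean = mu, variance = sum(fr * G^2) - mu^2)
}

# mean offspring value for each (mother, father) genotype pair: 4x4 matrix
offspring_mean_matrix <- function(locus) {
  TT <- transmission_matrix()
  TT %*% gvalue_matrix(locus) %*% t(TT)
}

#' Oracle covariances between relatives (exhaustive enumeration)
#'
#' Computes mother-offspring, father-offspring, full-sib and maternal/
#' paternal half-sib covariances of genotypic values directly from the
#' mating table: full sibs share both parents and are conditionally
#' independent given them; half sibs share exactly one parent, the other
#' parent of each offspring being an independent draw from the population.
#' Requires \code{f = 0} (the mixture is a marginal genotype model, not a
#' mating system, so relative covariances are only defined for the
#' random-mating population).
#'
#' @inheritParams alphas
#' @return Object of class \code{"relative_covariances"} with
#'   \code{approach = "oracle"}.
#' @export
oracle_relative_covariances <- function(locus, pop) {
  require_outbred(pop, "oracle_relative_covariances")
  fr <- genotype_frequencies(pop)
  G <- genotypic_values(locus)
  mu <- sum(fr * G)
  Gbar <- offspring_mean_matrix(locus)          # [mother, father]
  Gf <- as.vector(Gbar %*% fr)                  # mean offspring of mother g
  Gm <- as.vector(crossprod(fr, Gbar))          # mean offspring of father g
  structure(list(
    approach = "oracle",
    mother_offspring = sum(fr * G * Gf) - mu^2,
    father_offspring = sum(fr * G * Gm) - mu^2,
    fullsib = sum(outer(fr, fr) * Gbar^2) - mu^2,
    halfsib_maternal = sum(fr * Gf^2) - mu^2,
    halfsib_paternal = sum(fr * Gm^2) - mu^2),
    class = "relative_covariances")
}

#' Oracle Approach-1 breeding values from offspring means
#'
#' Reconstructs the offspring-mean breeding values by enumeration: the
#' female (male) breeding value of a genotype is twice the deviation of the
#' mean value of its offspring — as mother (father), mates drawn at random —
#' from the population mean. Equality with the closed-form Approach-1 table
#' is itself a test of the doubling convention.
#'
#' @inheritParams alphas
#' @return List with per-genotype vectors \code{female}, \code{male} and
#'   their mean \code{values}.
#' @export
oracle_breeding_values_A1 <- function(locus, pop) {
  require_outbred(pop, "oracle_breeding_values_A1")
  fr <- genotype_frequencies(pop)
  G <- genotypic_values(locus)
  mu <- sum(fr * G)
  Gbar <- offspring_mean_matrix(locus)
  female <- 2 * (as.vector(Gbar %*% fr) - mu)
  male <- 2 * (as.vector(crossprod(fr, Gbar)) - mu)
  names(female) <- names(male) <- GENOTYPES
  list(female = female, male = male, values = (female + male) / 2)
}

#' Oracle one-generation selection response by enumeration
#'
#' Weights each parental genotype by its relative fitness, forms the
#' sex-specific transmitted-allele frequencies, builds the offspring
#' genotype distribution respecting parental origin (maternal gamete fills
#' the maternal slot), and returns the offspring mean minus the parental
#' mean. Also reports the post-selection allele frequency and the oracle
#' version of the sex difference in offspring means (unselected mothers vs
#' unselected fathers, mates selected).
#'
#' @inheritParams fitness_table
#' @return Named numeric vector \code{c(delta_mu_f, delta_mu_m, p1_prime,
#'   offspring_mean_diff)}. The two response entries are computed through
#'   maternal and paternal accounting and agree identically.
#' @export
oracle_selection_response <- function(locus, pop, sel) {
  phi <- check_selection(locus, pop, sel)
  fr <- genotype_frequencies(pop)
  G <- genotypic_values(locus)
  mu <- sum(fr * G)
  frsel <- fr * phi / sum(fr * phi)
  TT <- transmission_matrix()
  pmat <- as.vector(crossprod(frsel, TT))  # transmitted-allele freq, mothers
  ppat <- pmat                             # fathers identical by symmetry
  Gmx <- gvalue_matrix(locus)
  # maternal accounting: sum over selected mothers of their gamete value paired
  # with the selected paternal allele pool; paternal accounting is the mirror
  dmu_f <- sum(frsel * (TT %*% (Gmx %*% ppat))) - mu
  dmu_m <- sum(frsel * (TT %*% crossprod(Gmx, pmat))) - mu
  # sex difference: offspring of unselected mothers (selected mates) minus
  # offspring of unselected fathers (selected mates)
  gf_prime <- sum(fr * (TT %*% Gmx %*% ppat))
  gm_prime <- sum(fr * (TT %*% t(Gmx) %*% pmat))
  c(delta_mu_f = dmu_f, delta_mu_m = dmu_m, p1_prime = pmat[1],
    offspring_mean_diff = gf_prime - gm_prime)
}

#' Oracle sex-specific 2b components from the exact genotype distribution
#'
#' Builds the Approach-2b construction numerically on the exact (possibly
#' inbred) genotype distribution: parental-origin additive effects as
#' conditional means, breeding values as their sums, dominance deviations as
#' residuals, then exact frequency-weighted variances and covariances. This
#' validates both the outbred Table of components and the inbreeding
#' closed forms without using either.
#'
#' @inheritParams alphas
#' @return Object of class \code{"inbred_variance_components"}.
#' @export
oracle_components_2b <- function(locus, pop) {
  fr <- genotype_frequencies(pop)
  frmx <- matrix(0, 2, 2)
  frmx[cbind(GENO_MAT, GENO_PAT)] <- fr
  Gmx <- gvalue_matrix(locus)
  mu <- sum(frmx * Gmx)
  eps_mat <- rowSums(frmx * Gmx) / rowSums(frmx) - mu
  eps_pat <- colSums(frmx * Gmx) / colSums(frmx) - mu
  Af <- outer(eps_mat, eps_mat, "+")
  Am <- outer(eps_pat, eps_pat, "+")
  Lf <- Gmx - mu - Af
  Lm <- Gmx - mu - Am
  structure(list(
    sigma2_A_f_I = sum(frmx * Af^2),
    sigma2_A_m_I = sum(frmx * Am^2),
    sigma2_D_f_I = sum(frmx * Lf^2),
    sigma2_D_m_I = sum(frmx * Lm^2),
    sigma_AD_f_I = sum(frmx * Af * Lf),
    sigma_AD_m_I = sum(frmx * Am * Lm),
    sigma2_G_I = sum(frmx * Gmx^2) - mu^2),
    class = "inbred_variance_components")
}

#' Sample a synthetic population of ordered genotypes
#'
#' Draws \code{n} individuals i.i.d. from the (possibly inbred) genotype
#' distribution, storing the maternal/paternal allele of each. Identical
#' seeds give identical populations.
#'
#' @inheritParams alphas
#' @param n number of individuals (at least 1).
#' @param seed integer seed for the draw.
#' @return Object of class \code{"simulated_population"}: list with
#'   \code{maternal}, \code{paternal} (integer allele vectors), \code{g}
#'   (genotypic values), \code{counts} (per-genotype tallies), \code{locus},
#'   \code{pop}, \code{n}, \code{seed}.
#' @export
sample_population <- function(locus, pop, n, seed) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(4L, n, replace = TRUE, prob = genotype_frequencies(pop))
  G <- genotypic_values(locus)
  structure(list(maternal = GENO_MAT[idx], paternal = GENO_PAT[idx],
                 g = as.numeric(G[idx]), counts = tabulate(idx, 4L),
                 locus = locus, pop = pop, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf("Simulated population: n = %d, seed = %d\n", x$n, x$seed))
  cat("genotype counts:\n")
  print(stats::setNames(x$counts, GENOTYPES))
  invisible(x)
}

#' Monte Carlo estimates of variance components from a sampled population
#'
#' Applies the Approach-2a/2b construction to the empirical genotype
#' distribution of a [sample_population()] draw: parental-origin additive
#' effects as empirical conditional means, dominance deviations as
#' residuals, then sample (frequency-weighted) variances and covariances.
#' On the exact distribution this reproduces the closed forms exactly; on a
#' sample it converges at the usual root-n rate. A monomorphic sample yields
#' \code{NA} components with a warning.
#'
#' @param simpop a [sample_population()] result.
#' @param approach \code{"A2b"} (sex-specific, default) or \code{"A2a"}.
#' @return For \code{"A2b"}, a list with \code{sigma2_A_f}, \code{sigma2_A_m},
#'   \code{sigma2_D_f}, \code{sigma2_D_m}, \code{sigma_AD_f},
#'   \code{sigma_AD_m}, \code{sigma2_G}, \code{mu}, \code{p1_hat}; for
#'   \code{"A2a"}, \code{sigma2_A}, \code{sigma2_D}, \code{sigma2_G},
#'   \code{mu}, \code{p1_hat}.
#' @export
empirical_components <- function(simpop, approach = c("A2b", "A2a")) {
  stopifnot(inherits(simpop, "simulated_population"))
  approach <- match.arg(approach)
  cnt <- simpop$counts
  n <- simpop$n
  frmx <- matrix(0, 2, 2)
  frmx[cbind(GENO_MAT, GENO_PAT)] <- cnt / n
  mat_marg <- rowSums(frmx); pat_marg <- colSums(frmx)
  p1_hat <- (mat_marg[1] + pat_marg[1]) / 2
  if (any(mat_marg == 0) || any(pat_marg == 0)) {
    warning("sample is monomorphic for one parental origin; components are NA")
    na <- NA_real_
    return(if (approach == "A2b")
      list(sigma2_A_f = na, sigma2_A_m = na, sigma2_D_f = na, sigma2_D_m = na,
           sigma_AD_f = na, sigma_AD_m = na, sigma2_G = na, mu = na,
           p1_hat = p1_hat)
      else list(sigma2_A = na, sigma2_D = na, sigma2_G = na, mu = na,
                p1_hat = p1_hat))
  }
  Gmx <- gvalue_matrix(simpop$locus)
  mu <- sum(frmx * Gmx)
  s2G <- sum(frmx * Gmx^2) - mu^2
  eps_mat <- rowSums(frmx * Gmx) / mat_marg - mu
  eps_pat <- colSums(frmx * Gmx) / pat_marg - mu
  if (approach == "A2b") {
    Af <- outer(eps_mat, eps_mat, "+")
    Am <- outer(eps_pat, eps_pat, "+")
    Lf <- Gmx - mu - Af; Lm <- Gmx - mu - Am
    list(sigma2_A_f = sum(frmx * Af^2), sigma2_A_m = sum(frmx * Am^2),
         sigma2_D_f = sum(frmx * Lf^2), sigma2_D_m = sum(frmx * Lm^2),
         sigma_AD_f = sum(frmx * Af * Lf), sigma_AD_m = sum(frmx * Am * Lm),
         sigma2_G = s2G, mu = mu, p1_hat = p1_hat)
  } else {
    A <- outer(eps_mat, eps_pat, "+")
    L <- Gmx - mu - A
    list(sigma2_A = sum(frmx * A^2), sigma2_D = sum(frmx * L^2),
         sigma2_G = s2G, mu = mu, p1_hat = p1_hat)
  }
}
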