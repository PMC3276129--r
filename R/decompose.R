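# Variance-decomposition approaches for an imprinted locus (f = 0).
#
# A1  : breeding values from offspring means (mating tables); sex-specific.
# A2a : additive effects conditioned on parental origin of each allele.
# A2b : like A2a but with separate female and male (generation-aware) terms;
#       identical output to A1.
# A3a : least-squares regression of genotypic value on A2-allele count.
# A3b : least-squares regression on separate maternal-origin and
#       paternal-origin A2 indicators.
# All five agree when k1 = k2 (Mendelian expression); they differ under
# imprinting, and only A1/A2b recover the additive-dominance covariance.

APPROACHES <- c("A1", "A2a", "A2b", "A3a", "A3b")

match_approach <- function(approach) {
  match.arg(approach, APPROACHES)
}

#' Breeding values under a chosen decomposition approach
#'
#' Per-genotype breeding values for one of the five approaches. The
#' sex-specific approaches (\code{A1}, \code{A2b}) carry separate female and
#' male values (e.g. female A1A1 is \code{-2 p2 alpha_f}); the genotype's
#' breeding value is their mean. \code{A2a} assigns reciprocal heterozygotes
#' different values (\code{p1 alpha_f - p2 alpha_m} vs
#' \code{-p2 alpha_f + p1 alpha_m}); \code{A3a} and \code{A3b} are the
#' regression constructions. Every approach shares the heterozygote mean
#' \code{(p1 - p2)(alpha_f + alpha_m)/2} and a frequency-weighted mean
#' breeding value of zero.
#'
#' @inheritParams alphas
#' @param approach one of \code{"A1"}, \code{"A2a"}, \code{"A2b"},
#'   \code{"A3a"}, \code{"A3b"}.
#' @return Object of class \code{"breeding_values"}: list with \code{approach},
#'   \code{values} (named per-genotype vector), \code{female}/\code{male}
#'   (for A1/A2b, else \code{NULL}) and \code{het_mean}.
#' @examples
#' loc <- imprinting_locus(1/2, 9/10, -8/10); pop <- population_state(1/2)
#' breeding_values(loc, pop, "A2a")
#' @export
breeding_values <- function(locus, pop, approach = "A1") {
  approach <- match_approach(approach)
  require_outbred(pop, "breeding_values")
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2; p1 <- pop$p1; p2 <- pop$p2
  al <- alphas(locus, pop); af <- al[["alpha_f"]]; am <- al[["alpha_m"]]
  female <- male <- NULL
  if (approach %in% c("A1", "A2b")) {
    female <- c(-2 * p2 * af, (p1 - p2) * af, (p1 - p2) * af, 2 * p1 * af)
    male   <- c(-2 * p2 * am, (p1 - p2) * am, (p1 - p2) * am, 2 * p1 * am)
    values <- (female + male) / 2
    names(female) <- names(male) <- GENOTYPES
  } else if (approach == "A2a") {
    values <- c(-p2 * (af + am), p1 * af - p2 * am, -p2 * af + p1 * am,
                p1 * (af + am))
  } else if (approach == "A3a") {
    values <- c(-p2 * (af + am), 0.5 * (p1 - p2) * (af + am),
                0.5 * (p1 - p2) * (af + am), p1 * (af + am))
  } else { # A3b
    values <- c(-p2 * (af + am),
                a * (p1 - p2 + k1 - 2 * p1 * p2 * (k1 + k2)),
                a * (p1 - p2 + k2 - 2 * p1 * p2 * (k1 + k2)),
                p1 * (af + am))
  }
  names(values) <- GENOTYPES
  structure(list(approach = approach, values = values,
                 female = female, male = male,
                 het_mean = 0.5 * (p1 - p2) * (af + am)),
            class = "breeding_values")
}

#' @export
print.breeding_values <- function(x, ...) {
  cat("Breeding values (approach ", x$approach, ")\n", sep = "")
  print(round(x$values, 6))
  if (!is.null(x$female)) {
    cat("female:\n"); print(round(x$female, 6))
    cat("male:\n");   print(round(x$male, 6))
  }
  invisible(x)
}

#' Parental-origin additive effects (Approach 2a/2b, f = 0)
#'
#' Average effects of inheriting each allele maternally or paternally:
#' \code{eps_1mat = -p2 alpha_f}, \code{eps_2mat = p1 alpha_f},
#' \code{eps_1pat = -p2 alpha_m}, \code{eps_2pat = p1 alpha_m}. These are
#' deviations, so their allele-frequency-weighted means vanish.
#'
#' @inheritParams alphas
#' @return Named numeric vector \code{c(eps_1mat, eps_2mat, eps_1pat, eps_2pat)}.
#' @export
additive_effects_2a <- function(locus, pop) {
  require_outbred(pop, "additive_effects_2a")
  al <- alphas(locus, pop)
  c(eps_1mat = -pop$p2 * al[["alpha_f"]], eps_2mat = pop$p1 * al[["alpha_f"]],
    eps_1pat = -pop$p2 * al[["alpha_m"]], eps_2pat = pop$p1 * al[["alpha_m"]])
}

#' Dominance deviations (Approaches 2a and 2b, f = 0)
#'
#' Residuals of the genotypic values after removing the mean and the
#' parental-origin additive effects. Approach 2a uses one deviation per
#' genotype, \code{lambda_ij = G_ij - mu - eps_imat - eps_jpat}; Approach 2b
#' defines separate female and male deviations,
#' \code{lambda_ij_f = G_ij - mu - eps_imat - eps_jmat} and
#' \code{lambda_ij_m = G_ij - mu - eps_ipat - eps_jpat}, carrying the
#' sex-and-generation effect that makes A2b agree with A1. All deviations
#' have frequency-weighted mean zero. The remaining approaches define
#' dominance only at the variance level, so they are rejected here.
#'
#' @inheritParams breeding_values
#' @param approach \code{"A2a"} or \code{"A2b"}.
#' @return For \code{A2a}, a named per-genotype vector; for \code{A2b}, a
#'   list with elements \code{female} and \code{male}.
#' @export
dominance_deviations <- function(locus, pop, approach = c("A2a", "A2b")) {
  approach <- match.arg(approach)
  require_outbred(pop, "dominance_deviations")
  G <- genotypic_values(locus)
  mu <- population_mean(locus, pop)
  eps <- additive_effects_2a(locus, pop)
  emat <- eps[c("eps_1mat", "eps_2mat")]
  epat <- eps[c("eps_1pat", "eps_2pat")]
  if (approach == "A2a") {
    lam <- G - mu - emat[GENO_MAT] - epat[GENO_PAT]
    names(lam) <- GENOTYPES
    lam
  } else {
    lf <- G - mu - emat[GENO_MAT] - emat[GENO_PAT]
    lm_ <- G - mu - epat[GENO_MAT] - epat[GENO_PAT]
    names(lf) <- names(lm_) <- GENOTYPES
    list(female = lf, male = lm_)
  }
}

#' Variance components under a chosen decomposition approach
#'
#' Closed-form additive and dominance variances and additive-dominance
#' covariances. For \code{A1}/\code{A2b}:
#' \code{sigma2_A_f = 2 p1 p2 alpha_f^2}, \code{sigma2_A_m = 2 p1 p2 alpha_m^2},
#' \code{sigma2_D = a^2 p1 p2 ((k1-k2)^2 + p1 p2 (k1+k2)^2)},
#' \code{sigma_AD_f = a p1 p2 alpha_f (k2-k1)},
#' \code{sigma_AD_m = a p1 p2 alpha_m (k1-k2)}.
#' \code{A2a}/\code{A3b} pool the sexes (\code{sigma2_A = p1 p2 (alpha_f^2 +
#' alpha_m^2)}, \code{sigma2_D = (a p1 p2 (k1+k2))^2}) and have zero AD
#' covariance by construction; \code{A3a} uses the single-regression forms.
#' Every approach partitions the same total \code{sigma2_G}: for A1/A2b,
#' \code{(sigma2_A_f + sigma2_A_m)/2 + sigma2_D + sigma_AD_f + sigma_AD_m};
#' for the pooled approaches, \code{sigma2_A + sigma2_D}.
#'
#' For A1/A2b the pooled slot \code{sigma2_A} is filled with
#' \code{(sigma2_A_f + sigma2_A_m)/2}, the additive variance that enters the
#' narrow-sense heritability.
#'
#' @inheritParams breeding_values
#' @return Object of class \code{"variance_components"}: list with
#'   \code{approach}, \code{sigma2_A_f}, \code{sigma2_A_m} (NA for pooled
#'   approaches), \code{sigma2_A}, \code{sigma2_D}, \code{sigma_AD_f},
#'   \code{sigma_AD_m}, \code{sigma2_G}.
#' @examples
#' loc <- imprinting_locus(1/2, 9/10, -8/10); pop <- population_state(1/2)
#' variance_components(loc, pop, "A1")
#' @export
variance_components <- function(locus, pop, approach = "A1") {
  approach <- match_approach(approach)
  require_outbred(pop, "variance_components")
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2; p1 <- pop$p1; p2 <- pop$p2
  al <- alphas(locus, pop); af <- al[["alpha_f"]]; am <- al[["alpha_m"]]
  s2G <- total_genetic_variance(locus, pop)
  if (approach %in% c("A1", "A2b")) {
    s2Af <- 2 * p1 * p2 * af^2
    s2Am <- 2 * p1 * p2 * am^2
    out <- list(sigma2_A_f = s2Af, sigma2_A_m = s2Am,
                sigma2_A = (s2Af + s2Am) / 2,
                sigma2_D = a^2 * p1 * p2 * ((k1 - k2)^2 + p1 * p2 * (k1 + k2)^2),
                sigma_AD_f = a * p1 * p2 * af * (k2 - k1),
                sigma_AD_m = a * p1 * p2 * am * (k1 - k2))
  } else if (approach %in% c("A2a", "A3b")) {
    out <- list(sigma2_A_f = NA_real_, sigma2_A_m = NA_real_,
                sigma2_A = p1 * p2 * (af^2 + am^2),
                sigma2_D = (a * p1 * p2 * (k1 + k2))^2,
                sigma_AD_f = 0, sigma_AD_m = 0)
  } else { # A3a
    out <- list(sigma2_A_f = NA_real_, sigma2_A_m = NA_real_,
                sigma2_A = 0.5 * p1 * p2 * (af + am)^2,
                sigma2_D = 0.5 * a^2 * p1 * p2 *
                  ((k1 - k2)^2 + 2 * p1 * p2 * (k1 + k2)^2),
                sigma_AD_f = 0, sigma_AD_m = 0)
  }
  structure(c(list(approach = approach), out, list(sigma2_G = s2G)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat("Variance components (approach ", x$approach, ")\n", sep = "")
  v <- unlist(x[setdiff(names(x), "approach")])
  print(round(v, digits))
  invisible(x)
}

#' Covariances between relatives under a chosen decomposition approach
#'
#' Mother-offspring, father-offspring, full-sib and half-sib covariances of
#' genotypic values under random mating. For \code{A1}/\code{A2b} the
#' sex-split forms are
#' \code{cov(mother, offspring) = p1 p2 alpha_f (alpha_f + alpha_m)/2},
#' \code{cov(father, offspring) = p1 p2 alpha_m (alpha_f + alpha_m)/2},
#' maternal/paternal half-sib \code{p1 p2 alpha_f^2 / 2} and
#' \code{p1 p2 alpha_m^2 / 2}, and full-sib
#' \code{p1 p2 (2(alpha_f^2 + alpha_m^2) + a^2 p1 p2 (k1+k2)^2)/4}.
#' For the pooled approaches the covariances follow the standard kinship
#' identities \code{parent-offspring = sigma2_A / 2},
#' \code{full-sib = sigma2_A / 2 + sigma2_D / 4} and
#' \code{half-sib = sigma2_A / 4} applied to that approach's components.
#' (Some published tabulations of the pooled-approach rows interchange the
#' full-sib and half-sib entries; the forms used here are the ones consistent
#' with the kinship identities and are verified against exhaustive
#' mating-table enumeration, see [oracle_relative_covariances()].)
#'
#' @inheritParams breeding_values
#' @return Object of class \code{"relative_covariances"}: list with
#'   \code{approach}, \code{mother_offspring}, \code{father_offspring},
#'   \code{fullsib}, \code{halfsib_maternal}, \code{halfsib_paternal}.
#' @export
relative_covariances <- function(locus, pop, approach = "A1") {
  approach <- match_approach(approach)
  require_outbred(pop, "relative_covariances")
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2; p1 <- pop$p1; p2 <- pop$p2
  al <- alphas(locus, pop); af <- al[["alpha_f"]]; am <- al[["alpha_m"]]
  if (approach %in% c("A1", "A2b")) {
    out <- list(mother_offspring = 0.5 * p1 * p2 * af * (af + am),
                father_offspring = 0.5 * p1 * p2 * am * (af + am),
                fullsib = 0.25 * p1 * p2 *
                  (2 * (af^2 + am^2) + a^2 * p1 * p2 * (k1 + k2)^2),
                halfsib_maternal = 0.5 * p1 * p2 * af^2,
                halfsib_paternal = 0.5 * p1 * p2 * am^2)
  } else {
    vc <- variance_components(locus, pop, approach)
    po <- vc$sigma2_A / 2
    fs <- vc$sigma2_A / 2 + vc$sigma2_D / 4
    hs <- vc$sigma2_A / 4
    out <- list(mother_offspring = po, father_offspring = po,
                fullsib = fs, halfsib_maternal = hs, halfsib_paternal = hs)
  }
  structure(c(list(approach = approach), out), class = "relative_covariances")
}

#' @export
print.relative_covariances <- function(x, digits = 4, ...) {
  cat("Covariances between relatives (approach ", x$approach, ")\n", sep = "")
  v <- unlist(x[setdiff(names(x), "approach")])
  print(round(v, digits))
  invisible(x)
}

#' Regression reconstruction of A3a/A3b breeding values
#'
#' Realises the regression approaches explicitly as frequency-weighted
#' least-squares fits: \code{A3a} regresses the genotypic value on the count
#' of A2 alleles (one slope); \code{A3b} on separate maternal-origin and
#' paternal-origin A2 indicators (two slopes). Breeding values are the fitted
#' values minus the population mean, and reproduce the closed forms returned
#' by [breeding_values()]. Requires a polymorphic population
#' (\code{0 < p1 < 1}) so the design has full column weight.
#'
#' @inheritParams breeding_values
#' @param approach \code{"A3a"} or \code{"A3b"}.
#' @return Named per-genotype vector of breeding values.
#' @export
regression_breeding_values <- function(locus, pop, approach = c("A3a", "A3b")) {
  approach <- match.arg(approach)
  require_outbred(pop, "regression_breeding_values")
  if (pop$p1 <= 0 || pop$p1 >= 1)
    stop("regression construction requires 0 < p1 < 1", call. = FALSE)
  G <- genotypic_values(locus)
  w <- genotype_frequencies(pop)
  dat <- data.frame(G = as.numeric(G),
                    x_mat = as.numeric(GENO_MAT == 2L),
                    x_pat = as.numeric(GENO_PAT == 2L))
  fit <- if (approach == "A3a") {
    stats::lm(G ~ I(x_mat + x_pat), data = dat, weights = w)
  } else {
    stats::lm(G ~ x_mat + x_pat, data = dat, weights = w)
  }
  bv <- stats::fitted(fit) - population_mean(locus, pop)
  names(bv) <- GENOTYPES
  bv
}
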