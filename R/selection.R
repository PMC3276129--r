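# One generation of selection under the linear fitness model
# phi_ij = 1 + G_ij * t, applied to a randomly mating (f = 0) population.

#' Linear fitness selection model
#'
#' Selection acts through the linear fitness function
#' \code{phi_ij = 1 + G_ij t}; \code{t} is the selection coefficient.
#' Positivity of every genotype's fitness depends on the locus, so it is
#' enforced where a locus is supplied (see [fitness_table()]).
#'
#' @param t selection coefficient; finite scalar.
#' @return Object of class \code{"selection_model"}.
#' @export
selection_model <- function(t) {
  check_scalar(t, "t")
  structure(list(t = t), class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("Linear fitness selection model: phi = 1 + G t, t = %g\n", x$t))
  invisible(x)
}

check_selection <- function(locus, pop, sel) {
  stopifnot(inherits(locus, "imprinting_locus"),
            inherits(pop, "population_state"),
            inherits(sel, "selection_model"))
  require_outbred(pop, "selection")
  phi <- 1 + genotypic_values(locus) * sel$t
  if (any(phi <= 0))
    stop("selection coefficient t = ", sel$t,
         " gives non-positive fitness for genotype ",
         paste(GENOTYPES[phi <= 0], collapse = ", "),
         "; all phi_ij = 1 + G_ij t must be positive", call. = FALSE)
  phi
}

# Table of per-parent-genotype offspring means; mate allele frequencies
# (q1, q2) may be pre- or post-selection.
offmean_cells <- function(locus, q1, q2) {
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2
  mat <- c(a * q2 * (1 + k2),
           0.5 * a * (q1 * (1 + k1) + q2 * (3 + k2)),
           0.5 * a * (q1 * (1 + k1) + q2 * (3 + k2)),
           a * (q1 * (1 + k1) + 2 * q2))
  pat <- c(a * q2 * (1 + k1),
           0.5 * a * (q1 * (1 + k2) + q2 * (3 + k1)),
           0.5 * a * (q1 * (1 + k2) + q2 * (3 + k1)),
           a * (q1 * (1 + k2) + 2 * q2))
  names(mat) <- names(pat) <- GENOTYPES
  list(maternal = mat, paternal = pat)
}

#' Fitness table under the linear selection model
#'
#' Per-genotype absolute fitness \code{phi_ij}, relative fitness
#' \code{w_ij = phi_ij / phibar}, genotype frequencies before and after
#' selection, and the mean offspring value of each parental genotype (by
#' parental sex) with mates drawn before or after selection. The mean
#' fitness satisfies \code{phibar = 1 + t mu}.
#'
#' @inheritParams alphas
#' @param sel a [selection_model()].
#' @return Data frame with one row per ordered genotype and columns
#'   \code{genotype}, \code{G}, \code{freq}, \code{phi}, \code{w},
#'   \code{freq_sel}, \code{offmean_mat}, \code{offmean_pat},
#'   \code{offmean_mat_sel}, \code{offmean_pat_sel}; attribute
#'   \code{mean_fitness}.
#' @export
fitness_table <- function(locus, pop, sel) {
  phi <- check_selection(locus, pop, sel)
  fr <- genotype_frequencies(pop)
  phibar <- sum(fr * phi)
  pre <- offmean_cells(locus, pop$p1, pop$p2)
  pp <- allele_freqs_after_selection(locus, pop, sel)
  post <- offmean_cells(locus, pp[["p1_prime"]], pp[["p2_prime"]])
  out <- data.frame(genotype = GENOTYPES, G = as.numeric(genotypic_values(locus)),
                    freq = as.numeric(fr), phi = as.numeric(phi),
                    w = as.numeric(phi / phibar),
                    freq_sel = as.numeric(fr * phi / phibar),
                    offmean_mat = as.numeric(pre$maternal),
                    offmean_pat = as.numeric(pre$paternal),
                    offmean_mat_sel = as.numeric(post$maternal),
                    offmean_pat_sel = as.numeric(post$paternal))
  attr(out, "mean_fitness") <- phibar
  out
}

#' Allele frequencies after one round of selection
#'
#' The closed-form post-selection frequencies
#' \code{p1' = p1 (2 + a p2 t (2 + k1 + k2)) / (2 phibar)} and
#' \code{p2' = p2 (2 + a t (4 + p1 (k1 + k2 - 2))) / (2 phibar)}, which sum
#' to one.
#'
#' @inheritParams fitness_table
#' @return Named numeric vector \code{c(p1_prime, p2_prime)}.
#' @export
allele_freqs_after_selection <- function(locus, pop, sel) {
  check_selection(locus, pop, sel)
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2
  p1 <- pop$p1; p2 <- pop$p2; t <- sel$t
  phibar <- 1 + a * p2 * t * (2 + p1 * (k1 + k2))
  c(p1_prime = p1 * (2 + a * p2 * t * (2 + k1 + k2)) / (2 * phibar),
    p2_prime = p2 * (2 + a * t * (4 + p1 * (-2 + k1 + k2))) / (2 * phibar))
}

#' Offspring means by parental genotype and sex
#'
#' Mean genotypic value of offspring of each parental genotype, by parental
#' sex, with mates drawn from the population before or after selection.
#' Before selection the frequency-weighted offspring mean equals the
#' population mean for both sexes.
#'
#' @inheritParams fitness_table
#' @return List with elements \code{before} and \code{after}, each a list of
#'   named per-genotype vectors \code{maternal} and \code{paternal}.
#' @export
offspring_means <- function(locus, pop, sel) {
  check_selection(locus, pop, sel)
  pp <- allele_freqs_after_selection(locus, pop, sel)
  list(before = offmean_cells(locus, pop$p1, pop$p2),
       after = offmean_cells(locus, pp[["p1_prime"]], pp[["p2_prime"]]))
}

#' Sex difference in post-selection offspring means
#'
#' \code{Gbar_f' - Gbar_m' = a p1 p2 t (k2 - k1)(alpha_f + alpha_m) /
#' (2 phibar)}: the offspring mean of unselected mothers mated to selected
#' partners minus that of unselected fathers. Zero exactly when
#' \code{k1 = k2} (no imprinting); antisymmetric under swapping \code{k1}
#' and \code{k2}.
#'
#' @inheritParams fitness_table
#' @return Scalar difference on the trait scale.
#' @export
offspring_mean_sex_difference <- function(locus, pop, sel) {
  check_selection(locus, pop, sel)
  a <- locus$a; p1 <- pop$p1; p2 <- pop$p2; t <- sel$t
  al <- alphas(locus, pop)
  phibar <- 1 + sel$t * population_mean(locus, pop)
  0.5 * a * p1 * p2 * t * (locus$k2 - locus$k1) *
    (al[["alpha_f"]] + al[["alpha_m"]]) / phibar
}

#' Exact response to selection for an imprinted trait
#'
#' One generation of selection under the linear fitness model. The exact
#' response is
#' \code{delta_mu = t gamma (phibar - t psi / 2) / phibar^2}
#' with \code{gamma = (sigma2_A_f + sigma_AD_f + sigma2_A_m + sigma_AD_m)/2}
#' and \code{psi = a p1 p2 (k1 + k2)} (components from Approach 1/2b). The
#' maternal and paternal accountings give the same response, and the formula
#' agrees with the exact enumeration recursion
#' \code{mu(p1') - mu(p1)} to machine precision (see
#' [oracle_selection_response()]). Note \code{psi^2 = sigma2_D + sigma_AD_f +
#' sigma_AD_m}: the composite entering the response is the signed square
#' root of that component sum.
#'
#' Also returned: the selection differential \code{S = t sigma2_G / phibar},
#' the breeder's-equation prediction \code{t sigma2_A(1) / phibar} with
#' \code{sigma2_A(1) = (sigma2_A_f + sigma2_A_m)/2} and the narrow-sense
#' heritability \code{h2 = sigma2_A(1) / sigma2_G} (see
#' [breeders_prediction()]), the post-selection allele frequencies, and the
#' sex difference in offspring means.
#'
#' @inheritParams fitness_table
#' @return Object of class \code{"selection_response"}: list with
#'   \code{mean_fitness}, \code{S}, \code{p1_prime}, \code{p2_prime},
#'   \code{delta_mu}, \code{delta_mu_f}, \code{delta_mu_m},
#'   \code{delta_mu_breeder}, \code{ratio_breeder_true},
#'   \code{offspring_mean_diff}, \code{psi}, \code{gamma}, \code{h2}.
#' @examples
#' loc <- imprinting_locus(1/2, 1/2, -1/2)
#' response_to_selection(loc, population_state(1/2), selection_model(1))
#' @export
response_to_selection <- function(locus, pop, sel) {
  check_selection(locus, pop, sel)
  a <- locus$a; p1 <- pop$p1; p2 <- pop$p2; t <- sel$t
  vc <- variance_components(locus, pop, "A1")
  mu <- population_mean(locus, pop)
  phibar <- 1 + t * mu
  psi <- a * p1 * p2 * (locus$k1 + locus$k2)
  gamma <- 0.5 * (vc$sigma2_A_f + vc$sigma_AD_f + vc$sigma2_A_m + vc$sigma_AD_m)
  dmu <- t * gamma * (phibar - 0.5 * t * psi) / phibar^2
  pp <- allele_freqs_after_selection(locus, pop, sel)
  breeder <- t * vc$sigma2_A / phibar
  structure(list(
    mean_fitness = phibar,
    S = t * vc$sigma2_G / phibar,
    p1_prime = pp[["p1_prime"]], p2_prime = pp[["p2_prime"]],
    delta_mu = dmu, delta_mu_f = dmu, delta_mu_m = dmu,
    delta_mu_breeder = breeder,
    ratio_breeder_true = if (dmu != 0) breeder / dmu else NA_real_,
    offspring_mean_diff = offspring_mean_sex_difference(locus, pop, sel),
    psi = psi, gamma = gamma,
    h2 = if (vc$sigma2_G > 0) vc$sigma2_A / vc$sigma2_G else NA_real_),
    class = "selection_response")
}

#' @export
print.selection_response <- function(x, digits = 6, ...) {
  cat("Response to one generation of selection (linear fitness)\n")
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

#' Breeder's-equation prediction of the response
#'
#' \code{Delta mu = h2 S = t sigma2_A(1) / phibar}, using the Approach-1/2b
#' additive variance \code{sigma2_A(1) = (sigma2_A_f + sigma2_A_m)/2}. The
#' prediction equals the true response only when both the dominance variance
#' and the additive-dominance covariances vanish (\code{k1 = k2 = 0}). Under
#' imprinting without dominance (\code{k1 = -k2}) the prediction exceeds the
#' true response by the exact factor \code{1 + k1^2} — double at complete
#' inactivation — and the closed specialisations
#' \code{2 a^2 p1 p2 t (1 + k1^2)/(1 + 2 a p2 t)} (prediction) and
#' \code{2 a^2 p1 p2 t/(1 + 2 a p2 t)} (true) are reported. With dominance
#' but no imprinting (\code{k1 = k2 = k != 0}) the prediction is an
#' overestimate; when both act and \code{|k1 - k2|} is small the sign of the
#' discrepancy can flip, so no global inequality is asserted.
#'
#' @inheritParams fitness_table
#' @return List with \code{prediction}, \code{h2}, \code{S}, and (when the
#'   parameter regime applies, else \code{NA}) \code{no_dominance_prediction},
#'   \code{no_dominance_true}, \code{no_imprinting_prediction}.
#' @export
breeders_prediction <- function(locus, pop, sel) {
  check_selection(locus, pop, sel)
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2
  p1 <- pop$p1; p2 <- pop$p2; t <- sel$t
  vc <- variance_components(locus, pop, "A1")
  phibar <- 1 + t * population_mean(locus, pop)
  pred <- t * vc$sigma2_A / phibar
  no_dom_pred <- no_dom_true <- no_imp_pred <- NA_real_
  if (k1 == -k2) {
    no_dom_pred <- 2 * a^2 * p1 * p2 * t * (1 + k1^2) / (1 + 2 * a * p2 * t)
    no_dom_true <- 2 * a^2 * p1 * p2 * t / (1 + 2 * a * p2 * t)
  }
  if (k1 == k2) {
    alpha <- a * (1 + k1 * (p1 - p2))
    no_imp_pred <- t * 2 * p1 * p2 * alpha^2 /
      (1 + 2 * a * p2 * t * (1 + k1 * p1))
  }
  list(prediction = pred,
       h2 = if (vc$sigma2_G > 0) vc$sigma2_A / vc$sigma2_G else NA_real_,
       S = t * vc$sigma2_G / phibar,
       no_dominance_prediction = no_dom_pred,
       no_dominance_true = no_dom_true,
       no_imprinting_prediction = no_imp_pred)
}

#' Iterate the closed-form selection response over generations
#'
#' Applies the one-generation closed forms repeatedly, updating the allele
#' frequency via [allele_freqs_after_selection()] after each generation (the
#' variance components are re-derived at the updated frequency each step).
#' The single-generation analysis is the exact result; iteration is a
#' convenience extrapolation.
#'
#' @inheritParams fitness_table
#' @param generations number of generations to iterate (default 1).
#' @return Data frame with one row per generation: \code{generation},
#'   \code{p1}, \code{mu}, \code{delta_mu}, \code{delta_mu_breeder}.
#' @export
iterate_selection <- function(locus, pop, sel, generations = 1) {
  stopifnot(generations >= 1)
  p1 <- pop$p1
  rows <- vector("list", generations)
  for (g in seq_len(generations)) {
    pg <- population_state(p1, 0)
    resp <- response_to_selection(locus, pg, sel)
    rows[[g]] <- data.frame(generation = g, p1 = p1,
                            mu = population_mean(locus, pg),
                            delta_mu = resp$delta_mu,
                            delta_mu_breeder = resp$delta_mu_breeder)
    p1 <- resp$p1_prime
  }
  do.call(rbind, rows)
}

#' Prediction with a separate imprinting-variance term (not implemented)
#'
#' A published alternative predicts the response as
#' \code{S (h2 + sigma_p^2 / 2)} where \code{sigma_p^2} is "the variance due
#' to imprinted genes". That quantity has no computable definition within
#' the one-locus model implemented here, so this function is a documented
#' stub that always signals an error.
#'
#' @param ... ignored.
#' @export
devries_prediction <- function(...) {
  stop("not implemented: the imprinting variance sigma_p^2 entering this ",
       "prediction has no computable definition in the one-locus model",
       call. = FALSE)
}
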