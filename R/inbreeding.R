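# Inbreeding extension of the sex-specific (Approach 2b) decomposition.
# The inbred population is the exact two-group mixture: proportion 1-f in
# Hardy-Weinberg proportions, proportion f fully homozygous. f is a fixed
# population parameter, not iterated across generations.

#' Population mean under inbreeding and imprinting
#'
#' \code{mu(I) = a p2 (2 + p1 (1-f)(k1+k2))}, the mixture-frequency-weighted
#' mean. Reduces to [population_mean()] at \code{f = 0} and to \code{2 a p2}
#' at \code{f = 1} (heterozygotes absent).
#'
#' @inheritParams alphas
#' @return Scalar mean on the trait scale.
#' @export
mean_inbred <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  locus$a * pop$p2 * (2 + pop$p1 * (1 - pop$f) * (locus$k1 + locus$k2))
}

#' Parental-origin additive effects under inbreeding
#'
#' The four average effects of inheriting each allele maternally or
#' paternally in the inbred mixture, e.g.
#' \code{eps_1mat(I) = -a p2 (1 + k1 p1 - k2 p2 + f(1 - k1 p1 + k2 p2))},
#' obtained as the conditional mean genotypic value given the inherited
#' allele minus \code{mu(I)}. Maternal- and paternal-origin effects each have
#' zero allele-frequency-weighted mean.
#'
#' @inheritParams alphas
#' @return Named numeric vector
#'   \code{c(eps_1mat, eps_2mat, eps_1pat, eps_2pat)}.
#' @export
inbred_additive_effects <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2
  p1 <- pop$p1; p2 <- pop$p2; f <- pop$f
  cf <- 1 + k1 * p1 - k2 * p2 + f * (1 - k1 * p1 + k2 * p2)
  cm <- 1 + k2 * p1 - k1 * p2 + f * (1 - k2 * p1 + k1 * p2)
  c(eps_1mat = -a * p2 * cf, eps_2mat = a * p1 * cf,
    eps_1pat = -a * p2 * cm, eps_2pat = a * p1 * cm)
}

#' Total genetic variance under inbreeding and imprinting
#'
#' \code{sigma2_G(I) = sigma2_G + f p1 p2 (4a^2 - alpha_f^2 - alpha_m^2)
#' - a^2 f^2 p1^2 p2^2 (k1+k2)^2}, where \code{sigma2_G} is the outbred total
#' variance. At \code{f = 1} this collapses to \code{4 a^2 p1 p2}. Without
#' dominance (\code{k1 = -k2}) the variance is linear in \code{f}; with
#' dominance it is quadratic.
#'
#' @inheritParams alphas
#' @return Scalar variance.
#' @export
total_variance_inbred <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  a <- locus$a; p1 <- pop$p1; p2 <- pop$p2; f <- pop$f
  al <- alphas(locus, pop); af <- al[["alpha_f"]]; am <- al[["alpha_m"]]
  s2G <- p1 * p2 * (af^2 + am^2 + a^2 * p1 * p2 * (locus$k1 + locus$k2)^2)
  s2G + f * p1 * p2 * (4 * a^2 - af^2 - am^2) -
    a^2 * f^2 * p1^2 * p2^2 * (locus$k1 + locus$k2)^2
}

#' Sex-specific variance components under inbreeding and imprinting
#'
#' The six closed-form components of the Approach-2b decomposition extended
#' to an inbred population: female and male additive variances
#' \code{sigma2_A_f(I) = 2 p1 p2 (1+f)(alpha_f + f(2a - alpha_f))^2} (male
#' analogous), female and male dominance variances (which differ between the
#' sexes once \code{f > 0}), and female and male additive-dominance
#' covariances. At \code{f = 0} each component reduces exactly to its
#' Approach-1/2b value; at \code{k1 = k2 = k} the two AD covariances coincide
#' at \code{-2 a^2 f p1 p2 (1 + f + k(1-f)(p1-p2))^2}, which is strictly
#' negative whenever \code{a f p1 p2 != 0} -- inbreeding alone always drags
#' the covariance negative, while imprinting can push one sex's covariance
#' positive.
#'
#' Each sex's components partition the total:
#' \code{sigma2_A_x(I) + sigma2_D_x(I) + 2 sigma_AD_x(I) = sigma2_G(I)}.
#'
#' @inheritParams alphas
#' @return Object of class \code{"inbred_variance_components"}: list with
#'   \code{sigma2_A_f_I}, \code{sigma2_A_m_I}, \code{sigma2_D_f_I},
#'   \code{sigma2_D_m_I}, \code{sigma_AD_f_I}, \code{sigma_AD_m_I},
#'   \code{sigma2_G_I}.
#' @examples
#' loc <- imprinting_locus(1/2, 1/2, -1/2)
#' inbred_variance_components(loc, population_state(1/2, f = 1/2))
#' @export
inbred_variance_components <- function(locus, pop) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  a <- locus$a; k1 <- locus$k1; k2 <- locus$k2
  p1 <- pop$p1; p2 <- pop$p2; f <- pop$f
  al <- alphas(locus, pop); af <- al[["alpha_f"]]; am <- al[["alpha_m"]]
  vc0 <- variance_components(locus, population_state(p1, 0), "A2b")
  s2D <- vc0$sigma2_D
  out <- list(
    sigma2_A_f_I = 2 * p1 * p2 * (1 + f) * (af + f * (2 * a - af))^2,
    sigma2_A_m_I = 2 * p1 * p2 * (1 + f) * (am + f * (2 * a - am))^2,
    sigma2_D_f_I = s2D + f * p1 * p2 *
      (af^2 - am^2 + 4 * (a - af) * (a - am) -
         f * (a^2 * p1 * p2 * (k1 + k2)^2 +
                2 * (2 * a - af) * (2 * a - 2 * af - am)) +
         2 * f^2 * (2 * a - af)^2),
    sigma2_D_m_I = s2D + f * p1 * p2 *
      (am^2 - af^2 + 4 * (a - af) * (a - am) -
         f * (a^2 * p1 * p2 * (k1 + k2)^2 +
                2 * (2 * a - am) * (2 * a - 2 * am - af)) +
         2 * f^2 * (2 * a - am)^2),
    sigma_AD_f_I = vc0$sigma_AD_f - f * p1 * p2 *
      (2 * a * (af - am) + 2 * af * am +
         f * (2 * a - af) * (3 * af + am + 2 * f * (2 * a - af))),
    sigma_AD_m_I = vc0$sigma_AD_m - f * p1 * p2 *
      (2 * a * (am - af) + 2 * af * am +
         f * (2 * a - am) * (3 * am + af + 2 * f * (2 * a - am))),
    sigma2_G_I = total_variance_inbred(locus, pop))
  structure(out, class = "inbred_variance_components")
}

#' @export
print.inbred_variance_components <- function(x, digits = 4, ...) {
  cat("Inbred variance components (Approach 2b extension)\n")
  print(round(unlist(x), digits))
  invisible(x)
}

#' Sweep the inbred variance components over f
#'
#' Evaluates [inbred_variance_components()] and [mean_inbred()] on a grid of
#' inbreeding coefficients, holding the locus and allele frequency fixed.
#'
#' @inheritParams alphas
#' @param f_values numeric vector of inbreeding coefficients in \code{[0, 1]}.
#' @return Data frame (class \code{"inbreeding_sweep"}) with one row per
#'   \code{f} and columns \code{f}, \code{mu_I}, the six components and
#'   \code{sigma2_G_I}.
#' @export
inbreeding_sweep <- function(locus, pop, f_values = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(locus, "imprinting_locus"), inherits(pop, "population_state"))
  rows <- lapply(f_values, function(f) {
    pf <- population_state(pop$p1, f)
    vc <- inbred_variance_components(locus, pf)
    data.frame(f = f, mu_I = mean_inbred(locus, pf), as.data.frame(unclass(vc)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("inbreeding_sweep", "data.frame")
  out
}

#' @export
plot.inbreeding_sweep <- function(x, ...) {
  opar <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(opar))
  graphics::matplot(x$f, x[, c("sigma2_G_I", "sigma2_A_f_I", "sigma2_A_m_I",
                               "sigma2_D_f_I", "sigma2_D_m_I")],
                    type = "l", lty = 1:5, col = 1:5,
                    xlab = "inbreeding coefficient f", ylab = "variance", ...)
  graphics::legend("topleft", bty = "n", lty = 1:5, col = 1:5,
                   legend = c("total", "additive (f)", "additive (m)",
                              "dominance (f)", "dominance (m)"))
  invisible(x)
}
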