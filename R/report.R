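# Reporting utilities: the two-scenario reference table of components and
# covariances, a randomized identity validator, and config parsing for the
# command-line interface.

# round half away from zero (the convention of the printed reference values;
# base round() is half-even and shows 0.03125 as 0.0312 instead of 0.0313)
round_half_up <- function(x, digits) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Reference table of variances and covariances for two inactivation scenarios
#'
#' Regenerates from the closed forms the standard two-scenario comparison of
#' all decomposition approaches: largely paternal inactivation
#' (\code{p1 = 1/2, a = 1/2, k1 = 9/10, k2 = -8/10}) and largely maternal
#' inactivation (\code{p1 = 1/3, a = 1/2, k1 = -7/10, k2 = 95/100}). Rows
#' are the additive variances (female/male), dominance variance,
#' additive-dominance covariances, offspring-parent, half-sib and full-sib
#' covariances; columns pair each scenario with the approach groups
#' \code{A1/2b}, \code{A2a/3b} and \code{A3a}. Values are rounded to
#' \code{digits} decimals with ties away from zero; pass \code{digits = NA}
#' for raw doubles.
#'
#' @param digits decimal places for rounding (default 4; NA for none).
#' @return Data frame with a \code{quantity} column and six value columns.
#' @examples
#' render_table6()
#' @export
render_table6 <- function(digits = 4) {
  scen <- list(
    paternal = list(locus = imprinting_locus(1/2, 9/10, -8/10),
                    pop = population_state(1/2)),
    maternal = list(locus = imprinting_locus(1/2, -7/10, 95/100),
                    pop = population_state(1/3)))
  col <- function(s, approach) {
    vc <- variance_components(s$locus, s$pop, approach)
    rc <- relative_covariances(s$locus, s$pop, approach)
    if (approach == "A1")
      c(vc$sigma2_A_f, vc$sigma2_A_m, vc$sigma2_D, vc$sigma_AD_f, vc$sigma_AD_m,
        rc$mother_offspring, rc$father_offspring,
        rc$halfsib_maternal, rc$halfsib_paternal, rc$fullsib)
    else
      c(vc$sigma2_A, NA, vc$sigma2_D, vc$sigma_AD_f, NA,
        rc$mother_offspring, NA, rc$halfsib_maternal, NA, rc$fullsib)
  }
  out <- data.frame(
    quantity = c("additive_variance_female", "additive_variance_male",
                 "dominance_variance", "AD_covariance_female",
                 "AD_covariance_male", "offspring_parent_female",
                 "offspring_parent_male", "halfsib_female", "halfsib_male",
                 "fullsib"),
    paternal_A1_2b = col(scen$paternal, "A1"),
    paternal_A2a_3b = col(scen$paternal, "A2a"),
    paternal_A3a = col(scen$paternal, "A3a"),
    maternal_A1_2b = col(scen$maternal, "A1"),
    maternal_A2a_3b = col(scen$maternal, "A2a"),
    maternal_A3a = col(scen$maternal, "A3a"))
  if (!is.na(digits))
    out[-1] <- lapply(out[-1], round_half_up, digits = digits)
  out
}

# draw a random parameter set with positive fitnesses; shared by the
# validator and the property tests
random_parameters <- function() {
  a <- stats::runif(1, -1.5, 1.5)
  locus <- imprinting_locus(a, stats::runif(1, -1, 1), stats::runif(1, -1, 1))
  pop <- population_state(stats::runif(1, 0.03, 0.97), stats::runif(1))
  G <- genotypic_values(locus)
  t <- stats::runif(1, -0.45, 0.45) / max(abs(G), 0.25)
  list(locus = locus, pop = pop,
       pop0 = population_state(pop$p1, 0), sel = selection_model(t))
}

#' Randomized validation of the algebraic identities
#'
#' Draws \code{grid_size} random parameter sets (trait scale, imprinting
#' coefficients, allele frequency, inbreeding coefficient, admissible
#' selection coefficient) and checks every algebraic identity the model
#' asserts: variance partitions for all five approaches; the
#' \code{alpha_f - alpha_m = a(k1-k2)} identity; the inbred-variance mixture
#' decomposition; mean fitness \code{1 + t mu}; post-selection frequencies
#' summing to one; equality of the maternal and paternal responses; the
#' closed-form response against the enumeration recursion; the closed-form
#' relative covariances against mating-table enumeration; and collapse of
#' all approaches to identical output at \code{k1 = k2}.
#'
#' @param grid_size number of random parameter sets (default 1000).
#' @param seed integer seed.
#' @param tol tolerance on each identity (default 1e-12).
#' @return Data frame with columns \code{identity}, \code{max_abs_error},
#'   \code{pass}; attribute \code{grid_size}.
#' @export
validate_identities <- function(grid_size = 1000, seed = 1, tol = 1e-12) {
  set.seed(seed)
  ids <- c("partition_A1_2b", "partition_A2a_3b", "partition_A3a",
           "alpha_difference", "inbred_mixture_decomposition",
           "inbred_components_vs_oracle", "mean_fitness",
           "freqs_after_selection_sum", "response_f_equals_m",
           "response_vs_oracle", "covariances_vs_oracle",
           "mendelian_collapse")
  worst <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_len(grid_size)) {
    pr <- random_parameters()
    locus <- pr$locus; pop0 <- pr$pop0; popI <- pr$pop; sel <- pr$sel
    a <- locus$a; k1 <- locus$k1; k2 <- locus$k2
    al <- alphas(locus, pop0)
    s2G <- total_genetic_variance(locus, pop0)
    v1 <- variance_components(locus, pop0, "A1")
    v2a <- variance_components(locus, pop0, "A2a")
    v3a <- variance_components(locus, pop0, "A3a")
    e <- c(partition_A1_2b = (v1$sigma2_A_f + v1$sigma2_A_m) / 2 + v1$sigma2_D +
             v1$sigma_AD_f + v1$sigma_AD_m - s2G,
           partition_A2a_3b = v2a$sigma2_A + v2a$sigma2_D - s2G,
           partition_A3a = v3a$sigma2_A + v3a$sigma2_D - s2G,
           alpha_difference = (al[["alpha_f"]] - al[["alpha_m"]]) -
             a * (k1 - k2))
    # inbred mixture decomposition of the total variance
    s2G1 <- 4 * a^2 * pop0$p1 * pop0$p2
    f <- popI$f
    mix <- (1 - f) * s2G + f * s2G1 + 0.5 * f * (1 - f) *
      (2 * v1$sigma2_D + 2 * v1$sigma_AD_f + 2 * v1$sigma_AD_m)
    e["inbred_mixture_decomposition"] <- total_variance_inbred(locus, popI) - mix
    vcI <- inbred_variance_components(locus, popI)
    vcO <- oracle_components_2b(locus, popI)
    e["inbred_components_vs_oracle"] <- max(abs(unlist(vcI) - unlist(vcO)))
    # selection identities
    ft <- fitness_table(locus, pop0, sel)
    e["mean_fitness"] <- attr(ft, "mean_fitness") -
      (1 + sel$t * population_mean(locus, pop0))
    pp <- allele_freqs_after_selection(locus, pop0, sel)
    e["freqs_after_selection_sum"] <- sum(pp) - 1
    resp <- response_to_selection(locus, pop0, sel)
    e["response_f_equals_m"] <- resp$delta_mu_f - resp$delta_mu_m
    orc <- oracle_selection_response(locus, pop0, sel)
    e["response_vs_oracle"] <- max(abs(c(resp$delta_mu - orc[["delta_mu_f"]],
                                         resp$delta_mu - orc[["delta_mu_m"]],
                                         resp$p1_prime - orc[["p1_prime"]])))
    rc <- relative_covariances(locus, pop0, "A1")
    ro <- oracle_relative_covariances(locus, pop0)
    e["covariances_vs_oracle"] <- max(abs(
      unlist(rc[-1]) - unlist(ro[-1])[names(rc)[-1]]))
    # Mendelian collapse: at k1 = k2 all approaches agree on everything
    lk <- imprinting_locus(a, k1, k1)
    bv <- lapply(APPROACHES, function(ap) breeding_values(lk, pop0, ap)$values)
    vk <- lapply(APPROACHES, function(ap) {
      v <- variance_components(lk, pop0, ap)
      c(v$sigma2_A, v$sigma2_D, v$sigma_AD_f, v$sigma_AD_m)
    })
    ck <- lapply(APPROACHES, function(ap) {
      unlist(relative_covariances(lk, pop0, ap)[-1])
    })
    e["mendelian_collapse"] <- max(
      vapply(bv[-1], function(x) max(abs(x - bv[[1]])), 0),
      vapply(vk[-1], function(x) max(abs(x - vk[[1]])), 0),
      vapply(ck[-1], function(x) max(abs(x - ck[[1]])), 0))
    worst <- pmax(worst, abs(e[ids]))
  }
  out <- data.frame(identity = ids, max_abs_error = as.numeric(worst),
                    pass = as.numeric(worst) <= tol, row.names = NULL)
  attr(out, "grid_size") <- grid_size
  out
}

#' Read a run configuration from JSON or YAML
#'
#' Accepts a config file whose keys are a subset of
#' \code{a, k1, k2, p1, f, t}; the format is chosen by extension
#' (\code{.json} vs \code{.yml}/\code{.yaml}). Unknown keys are an error.
#'
#' @param path path to the config file.
#' @return Named list of numeric parameters.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::fromJSON(path),
                yml = yaml::read_yaml(path),
                yaml = yaml::read_yaml(path),
                stop("unsupported config format '.", ext,
                     "'; use .json, .yml or .yaml", call. = FALSE))
  allowed <- c("a", "k1", "k2", "p1", "f", "t")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  lapply(cfg, as.numeric)
}

#' Write a data frame as TSV with an embedded parameter header
#'
#' Writes tab-delimited output with a header row; the parameter set used is
#' embedded as leading \code{#} comment lines so every output file records
#' its configuration.
#'
#' @param x data frame to write.
#' @param file output path or \code{""} for stdout.
#' @param params named list of parameters to embed (may be empty).
#' @return Invisibly, \code{x}.
#' @export
write_tsv_report <- function(x, file = "", params = list()) {
  con <- if (identical(file, "")) stdout() else file(file, "w")
  if (!identical(file, "")) on.exit(close(con))
  if (length(params))
    writeLines(paste0("# ", names(params), " = ",
                      vapply(params, format, "")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
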