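test_that("breeding values match the closed-form tables", {
  sc <- paternal_scenario()
  bv1 <- breeding_values(sc$locus, sc$pop, "A1")
  # A1A1 mean breeding value is -p2(alpha_f + alpha_m)
  expect_equal(bv1$values[["A1A1"]], -0.5)
  # sex-specific values: female A1A1 is -2 p2 alpha_f
  expect_equal(bv1$female[["A1A1"]], -0.925)
  expect_equal(bv1$male[["A1A1"]], -0.075)
  # A2a distinguishes reciprocal heterozygotes
  bv2a <- breeding_values(sc$locus, sc$pop, "A2a")
  expect_equal(bv2a$values[["A2A1"]], 0.425)
  expect_equal(bv2a$values[["A1A2"]], -0.425)
  # A1 and A2b are the same construction
  bv2b <- breeding_values(sc$locus, sc$pop, "A2b")
  expect_equal(bv1$values, bv2b$values)
  expect_equal(bv1$female, bv2b$female)
})

test_that("breeding values have zero mean and a shared heterozygote mean", {
  set.seed(41)
  for (i in 1:40) {
    pr <- draw_parameters()
    fr <- genotype_frequencies(pr$pop)
    al <- alphas(pr$locus, pr$pop)
    het <- 0.5 * (pr$pop$p1 - pr$pop$p2) * sum(al)
    for (ap in c("A1", "A2a", "A2b", "A3a", "A3b")) {
      bv <- breeding_values(pr$locus, pr$pop, ap)
      expect_equal(sum(fr * bv$values), 0, tolerance = 1e-12)
      expect_equal(mean(bv$values[c("A2A1", "A1A2")]), het, tolerance = 1e-12)
      expect_equal(bv$het_mean, het)
    }
    # Mendelian expression collapses all approaches to the same table
    lk <- imprinting_locus(pr$locus$a, pr$locus$k1, pr$locus$k1)
    tabs <- lapply(c("A1", "A2a", "A2b", "A3a", "A3b"),
                   function(ap) breeding_values(lk, pr$pop, ap)$values)
    for (tab in tabs[-1]) expect_equal(tab, tabs[[1]], tolerance = 1e-12)
  }
})

test_that("parental-origin additive effects are zero-mean deviations", {
  sc <- paternal_scenario()
  eps <- additive_effects_2a(sc$locus, sc$pop)
  expect_equal(eps[["eps_1mat"]], -0.4625)
  expect_equal(eps[["eps_2mat"]], 0.4625)
  eps0 <- additive_effects_2a(imprinting_locus(1/2, 0, 0), sc$pop)
  expect_equal(unname(eps0), c(-0.25, 0.25, -0.25, 0.25))
  set.seed(51)
  for (i in 1:30) {
    pr <- draw_parameters()
    e <- additive_effects_2a(pr$locus, pr$pop)
    p1 <- pr$pop$p1; p2 <- pr$pop$p2
    expect_equal(p1 * e[["eps_1mat"]] + p2 * e[["eps_2mat"]], 0,
                 tolerance = 1e-12)
    expect_equal(p1 * e[["eps_1pat"]] + p2 * e[["eps_2pat"]], 0,
                 tolerance = 1e-12)
  }
})

test_that("dominance deviations reproduce their variances and vanish without dominance", {
  expect_equal(unname(dominance_deviations(imprinting_locus(1, 0, 0),
                                           population_state(0.3), "A2a")),
               rep(0, 4))
  set.seed(61)
  for (i in 1:30) {
    pr <- draw_parameters()
    fr <- genotype_frequencies(pr$pop)
    lam <- dominance_deviations(pr$locus, pr$pop, "A2a")
    expect_equal(sum(fr * lam), 0, tolerance = 1e-12)
    # variance of the A2a deviations equals the closed-form A2a dominance variance
    expect_equal(sum(fr * lam^2),
                 (pr$locus$a * pr$pop$p1 * pr$pop$p2 *
                    (pr$locus$k1 + pr$locus$k2))^2, tolerance = 1e-12)
    l2b <- dominance_deviations(pr$locus, pr$pop, "A2b")
    expect_equal(sum(fr * l2b$female), 0, tolerance = 1e-12)
    expect_equal(sum(fr * l2b$male), 0, tolerance = 1e-12)
  }
  expect_error(dominance_deviations(imprinting_locus(1, 0, 0),
                                    population_state(0.3), "A1"))
})

test_that("variance components reproduce the reference scenarios", {
  sc <- paternal_scenario()
  vc <- variance_components(sc$locus, sc$pop, "A1")
  expect_printed(c(vc$sigma2_A_f, vc$sigma2_A_m, vc$sigma2_D,
                   vc$sigma_AD_f, vc$sigma_AD_m),
                 c(0.4278, 0.0028, 0.1808, -0.1966, 0.0159))
  vc3a <- variance_components(sc$locus, sc$pop, "A3a")
  expect_printed(c(vc3a$sigma2_A, vc3a$sigma2_D), c(0.1250, 0.0905))
  mc <- maternal_scenario()
  vcm <- variance_components(mc$locus, mc$pop, "A2b")
  expect_printed(c(vcm$sigma2_A_f, vcm$sigma2_A_m, vcm$sigma2_D,
                   vcm$sigma_AD_f, vcm$sigma_AD_m),
                 c(0.0020, 0.3534, 0.1520, 0.0122, -0.1635))
  # no imprinting or dominance: additive variance only
  v0 <- variance_components(imprinting_locus(1/2, 0, 0),
                            population_state(0.3), "A1")
  expect_equal(v0$sigma2_D, 0)
  expect_equal(v0$sigma_AD_f, 0)
  expect_equal(v0$sigma2_A_f, 2 * 0.3 * 0.7 * 0.25)
  expect_equal(v0$sigma2_A_f, v0$sigma2_A_m)
})

test_that("every approach partitions the same total variance", {
  set.seed(71)
  for (i in 1:60) {
    pr <- draw_parameters()
    s2G <- total_genetic_variance(pr$locus, pr$pop)
    v1 <- variance_components(pr$locus, pr$pop, "A1")
    expect_equal((v1$sigma2_A_f + v1$sigma2_A_m) / 2 + v1$sigma2_D +
                   v1$sigma_AD_f + v1$sigma_AD_m, s2G, tolerance = 1e-12)
    for (ap in c("A2a", "A3a", "A3b")) {
      v <- variance_components(pr$locus, pr$pop, ap)
      expect_equal(v$sigma2_A + v$sigma2_D, s2G, tolerance = 1e-12)
    }
    # the summed AD covariance is never positive; zero only when k1 = k2
    ad_sum <- v1$sigma_AD_f + v1$sigma_AD_m
    expect_equal(ad_sum, -pr$locus$a^2 * pr$pop$p1 * pr$pop$p2 *
                   (pr$locus$k1 - pr$locus$k2)^2, tolerance = 1e-12)
    expect_lte(ad_sum, 1e-15)
  }
})

test_that("relative covariances match the reference scenarios and symmetries", {
  sc <- paternal_scenario()
  rc <- relative_covariances(sc$locus, sc$pop, "A1")
  expect_printed(c(rc$mother_offspring, rc$father_offspring,
                   rc$halfsib_maternal, rc$halfsib_paternal, rc$fullsib),
                 c(0.1156, 0.0094, 0.1070, 0.0007, 0.1077))
  rc2a <- relative_covariances(sc$locus, sc$pop, "A2a")
  expect_printed(c(rc2a$mother_offspring, rc2a$halfsib_maternal, rc2a$fullsib),
                 c(0.1077, 0.0538, 0.1077))
  # Mendelian additive case: parent-offspring covariance is sigma2_A / 2
  rc0 <- relative_covariances(imprinting_locus(1/2, 0, 0),
                              population_state(1/2), "A1")
  expect_equal(rc0$mother_offspring, 0.0625)
  expect_equal(rc0$father_offspring, 0.0625)
  set.seed(81)
  for (i in 1:30) {
    pr <- draw_parameters()
    rc <- relative_covariances(pr$locus, pr$pop, "A1")
    sw <- relative_covariances(
      imprinting_locus(pr$locus$a, pr$locus$k2, pr$locus$k1), pr$pop, "A1")
    # swapping k1 and k2 swaps the maternal/paternal entries
    expect_equal(rc$mother_offspring, sw$father_offspring, tolerance = 1e-12)
    expect_equal(rc$halfsib_maternal, sw$halfsib_paternal, tolerance = 1e-12)
    expect_equal(rc$fullsib, sw$fullsib, tolerance = 1e-12)
  }
})

test_that("least-squares fits reproduce the regression-approach breeding values", {
  set.seed(91)
  for (i in 1:25) {
    pr <- draw_parameters()
    for (ap in c("A3a", "A3b")) {
      expect_equal(regression_breeding_values(pr$locus, pr$pop, ap),
                   breeding_values(pr$locus, pr$pop, ap)$values,
                   tolerance = 1e-9)
    }
  }
  # regression residual variance is that approach's dominance variance
  sc <- maternal_scenario()
  fr <- genotype_frequencies(sc$pop)
  G <- genotypic_values(sc$locus)
  mu <- population_mean(sc$locus, sc$pop)
  for (ap in c("A3a", "A3b")) {
    res <- G - mu - regression_breeding_values(sc$locus, sc$pop, ap)
    expect_equal(sum(fr * res^2),
                 variance_components(sc$locus, sc$pop, ap)$sigma2_D,
                 tolerance = 1e-9)
  }
})
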