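test_that("fitness table follows the linear fitness model", {
  loc <- imprinting_locus(1/2, 9/10, -8/10)
  pop <- population_state(1/2)
  ft <- fitness_table(loc, pop, selection_model(1))
  expect_equal(ft$phi, c(1, 1.95, 1.10, 2.0))
  expect_equal(sum(ft$freq_sel), 1, tolerance = 1e-12)
  # no selection: relative fitnesses one, frequencies unchanged
  ft0 <- fitness_table(loc, pop, selection_model(0))
  expect_equal(ft0$w, rep(1, 4))
  expect_equal(ft0$freq_sel, ft0$freq)
  # mean fitness is 1 + t mu
  set.seed(151)
  for (i in 1:30) {
    pr <- draw_parameters()
    ft <- fitness_table(pr$locus, pr$pop, pr$sel)
    expect_equal(attr(ft, "mean_fitness"),
                 1 + pr$sel$t * population_mean(pr$locus, pr$pop),
                 tolerance = 1e-12)
  }
  # inadmissible t: some genotype would have non-positive fitness
  expect_error(fitness_table(loc, pop, selection_model(-1)), "non-positive")
})

test_that("post-selection allele frequencies are exact and sum to one", {
  loc <- imprinting_locus(1/2, 1/2, -1/2)
  pp <- allele_freqs_after_selection(loc, population_state(1/2),
                                     selection_model(1))
  expect_equal(pp[["p1_prime"]], 5/12)
  set.seed(161)
  for (i in 1:40) {
    pr <- draw_parameters()
    pp <- allele_freqs_after_selection(pr$locus, pr$pop, pr$sel)
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    # neutral limit
    p0 <- allele_freqs_after_selection(pr$locus, pr$pop, selection_model(0))
    expect_equal(p0[["p1_prime"]], pr$pop$p1)
    # a t > 0 favours A2 on this scale, so p1 cannot increase
    if (pr$locus$a * pr$sel$t > 0)
      expect_lte(pp[["p1_prime"]], pr$pop$p1 + 1e-14)
    # matches the enumeration oracle
    orc <- oracle_selection_response(pr$locus, pr$pop, pr$sel)
    expect_equal(pp[["p1_prime"]], orc[["p1_prime"]], tolerance = 1e-12)
  }
})

test_that("offspring means reduce to the population mean before selection", {
  set.seed(171)
  for (i in 1:30) {
    pr <- draw_parameters()
    om <- offspring_means(pr$locus, pr$pop, pr$sel)
    fr <- genotype_frequencies(pr$pop)
    mu <- population_mean(pr$locus, pr$pop)
    expect_equal(sum(fr * om$before$maternal), mu, tolerance = 1e-12)
    expect_equal(sum(fr * om$before$paternal), mu, tolerance = 1e-12)
  }
  # A1A1 mother: offspring inherit A1 maternally, mate allele drawn at random
  loc <- imprinting_locus(1/2, 9/10, -8/10)
  om <- offspring_means(loc, population_state(0.3), selection_model(0))
  expect_equal(om$before$maternal[["A1A1"]], 0.5 * 0.7 * (1 - 0.8))
  # no imprinting: maternal and paternal rows coincide
  omk <- offspring_means(imprinting_locus(1/2, 0.4, 0.4),
                         population_state(0.3), selection_model(0.2))
  expect_equal(omk$before$maternal, omk$before$paternal)
  expect_equal(omk$after$maternal, omk$after$paternal)
})

test_that("sex difference in offspring means is antisymmetric in the k's", {
  loc <- imprinting_locus(1/2, 1/2, -1/2)
  pop <- population_state(1/2)
  d <- offspring_mean_sex_difference(loc, pop, selection_model(1))
  expect_equal(d, -1/24, tolerance = 1e-9)
  set.seed(181)
  for (i in 1:30) {
    pr <- draw_parameters()
    d <- offspring_mean_sex_difference(pr$locus, pr$pop, pr$sel)
    sw <- offspring_mean_sex_difference(
      imprinting_locus(pr$locus$a, pr$locus$k2, pr$locus$k1), pr$pop, pr$sel)
    expect_equal(sw, -d, tolerance = 1e-12)
    # agreement with gamete-accounting enumeration
    orc <- oracle_selection_response(pr$locus, pr$pop, pr$sel)
    expect_equal(d, orc[["offspring_mean_diff"]], tolerance = 1e-12)
    # vanishes without imprinting
    dk <- offspring_mean_sex_difference(
      imprinting_locus(pr$locus$a, pr$locus$k1, pr$locus$k1), pr$pop, pr$sel)
    expect_equal(dk, 0)
  }
})

test_that("closed-form response equals the exact one-generation recursion", {
  # imprinting without dominance: Delta mu = 2 a^2 p1 p2 t / (1 + 2 a p2 t)
  loc <- imprinting_locus(1/2, 1/2, -1/2)
  pop <- population_state(1/2)
  resp <- response_to_selection(loc, pop, selection_model(1))
  expect_equal(resp$delta_mu, 1/12, tolerance = 1e-12)
  set.seed(191)
  for (i in 1:50) {
    pr <- draw_parameters()
    resp <- response_to_selection(pr$locus, pr$pop, pr$sel)
    orc <- oracle_selection_response(pr$locus, pr$pop, pr$sel)
    expect_equal(resp$delta_mu, orc[["delta_mu_f"]], tolerance = 1e-12)
    expect_equal(resp$delta_mu_f, resp$delta_mu_m)
    # averaged-heterozygote equivalence: k = (k1 + k2)/2 gives the same response
    kbar <- (pr$locus$k1 + pr$locus$k2) / 2
    ravg <- response_to_selection(imprinting_locus(pr$locus$a, kbar, kbar),
                                  pr$pop, pr$sel)
    expect_equal(ravg$delta_mu, resp$delta_mu, tolerance = 1e-12)
    # t = 0: no response
    r0 <- response_to_selection(pr$locus, pr$pop, selection_model(0))
    expect_equal(r0$delta_mu, 0)
    expect_equal(r0$S, 0)
  }
  # purely additive locus: breeder's equation is exact
  radd <- response_to_selection(imprinting_locus(1/2, 0, 0),
                                population_state(0.3), selection_model(0.5))
  expect_equal(radd$delta_mu, radd$delta_mu_breeder, tolerance = 1e-12)
})

test_that("breeder's equation overestimates the response as expected", {
  # imprinting, no dominance: ratio is exactly 1 + k1^2, double at |k1| = 1
  set.seed(201)
  for (i in 1:30) {
    a <- runif(1, 0.2, 1); k1 <- runif(1, -1, 1); p1 <- runif(1, 0.1, 0.9)
    t <- runif(1, 0.05, 0.45) / (2 * a)
    loc <- imprinting_locus(a, k1, -k1)
    pop <- population_state(p1)
    resp <- response_to_selection(loc, pop, selection_model(t))
    expect_equal(resp$ratio_breeder_true, 1 + k1^2, tolerance = 1e-12)
  }
  loc1 <- imprinting_locus(1/2, 1, -1)
  resp1 <- response_to_selection(loc1, population_state(0.4),
                                 selection_model(0.8))
  expect_equal(resp1$ratio_breeder_true, 2, tolerance = 1e-12)
  bp <- breeders_prediction(imprinting_locus(1/2, 1/2, -1/2),
                            population_state(1/2), selection_model(1))
  expect_equal(bp$no_dominance_prediction, 0.1041667, tolerance = 1e-6)
  expect_equal(bp$no_dominance_true, 0.0833333, tolerance = 1e-6)
  # dominance without imprinting: the overshoot of the prediction is exactly
  # t^2 sigma2_A a k p1 p2 / phibar^2, so the prediction exceeds the true
  # response whenever the dominance deviation points along the selected
  # direction (a k t > 0), and undershoots when it opposes it
  for (k in seq(-0.9, 0.9, by = 0.3)) {
    if (abs(k) < 1e-8) next
    loc <- imprinting_locus(1/2, k, k)
    for (p1 in c(0.2, 0.5, 0.8)) {
      resp <- response_to_selection(loc, population_state(p1),
                                    selection_model(0.6))
      overshoot <- 0.6^2 * (resp$h2 * variance_components(
        loc, population_state(p1), "A1")$sigma2_G) *
        0.5 * k * p1 * (1 - p1) / resp$mean_fitness^2
      expect_equal(resp$delta_mu_breeder - resp$delta_mu, overshoot,
                   tolerance = 1e-12)
      if (k > 0) expect_gte(resp$delta_mu_breeder, resp$delta_mu - 1e-12)
      else expect_lte(resp$delta_mu_breeder, resp$delta_mu + 1e-12)
    }
  }
  # with both acting and small |k1 - k2| the discrepancy can flip sign: the
  # breeder's equation may underestimate, so no global inequality holds
  rflip <- response_to_selection(imprinting_locus(1/2, -0.08, 0.01),
                                 population_state(0.6), selection_model(1))
  expect_gt(rflip$delta_mu, rflip$delta_mu_breeder)
})

test_that("iterated selection tracks the closed-form recursion", {
  loc <- imprinting_locus(1/2, 1/2, -1/2)
  traj <- iterate_selection(loc, population_state(1/2), selection_model(1), 3)
  expect_equal(nrow(traj), 3)
  expect_equal(traj$p1[1], 0.5)
  expect_equal(traj$p1[2], 5/12)
  # mean moves by delta_mu each generation
  expect_equal(diff(traj$mu), head(traj$delta_mu, -1), tolerance = 1e-12)
  expect_error(devries_prediction(), "not implemented")
})
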