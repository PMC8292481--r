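test_that("case-only tables reproduce the published strata", {
  pairs <- as_stratum_pairs(local({
    df <- chek2_caseonly_strata(); df[df$stratum != "Combined", ]
  }))
  t_h2 <- case_only_table(pairs[["Helsinki2"]])
  expect_equal(unlist(t_h2[c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 26, 124, 841))
  expect_equal(round(as.numeric(sample_or(t_h2)), 2), 0.52)
  t_h1 <- case_only_table(pairs[["Helsinki1—unselected"]])
  expect_equal(unlist(t_h1[c("a", "b", "c", "d")], use.names = FALSE),
               c(4, 44, 241, 1432))
  expect_equal(round(as.numeric(sample_or(t_h1)), 2), 0.54)
  # identical genotype distributions give OR 1
  same <- stratum_pair("x", genotype_counts(80, 15, 5),
                       genotype_counts(160, 30, 10))
  expect_equal(as.numeric(sample_or(case_only_table(same))), 1)
  # allelic coding counts alleles
  ta <- case_only_table(pairs[["Helsinki2"]], coding = "allelic")
  expect_equal(ta$a, 2)
  expect_equal(ta$b, 54)
})

test_that("Mantel-Haenszel pooling: identities, frozen oracle, stats::mantelhaen", {
  t <- two_by_two(7, 13, 11, 17)
  one <- mantel_haenszel(t)
  expect_equal(one$pooled_or, as.numeric(sample_or(t)))
  # k copies of a stratum leave the pooled OR unchanged
  expect_equal(mantel_haenszel(rep(list(t), 5))$pooled_or, one$pooled_or)

  # six published strata, dominant coding: frozen direct-formula oracle
  mh <- mantel_haenszel(published_strata_tables())
  expect_equal(mh$pooled_or, 0.666581, tolerance = 1e-5)
  expect_equal(mh$ci_low, 0.445605, tolerance = 1e-5)
  expect_equal(mh$ci_high, 0.997140, tolerance = 1e-5)
  expect_equal(mh$p_value, 0.049336, tolerance = 1e-4)
  expect_true(mh$pooled_or >= 0.6 && mh$pooled_or <= 0.8)
  expect_equal(mh$n_strata, 6L)

  # randomized cross-check against stats::mantelhaen.test
  set.seed(123)
  for (i in 1:10) {
    strata <- replicate(sample(2:5, 1), random_two_by_two(60), simplify = FALSE)
    mine <- mantel_haenszel(strata)
    arr <- array(unlist(lapply(strata, function(t) c(t$a, t$b, t$c, t$d))),
                 dim = c(2, 2, length(strata)))
    ref <- stats::mantelhaen.test(aperm(arr, c(2, 1, 3)), correct = FALSE)
    expect_equal(mine$pooled_or, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    # pooled OR within the convex hull of defined per-stratum ORs
    ors <- vapply(strata, function(t) t$a * t$d / (t$b * t$c), numeric(1))
    expect_gte(mine$pooled_or, min(ors) - 1e-12)
    expect_lte(mine$pooled_or, max(ors) + 1e-12)
  }

  # strata with zero information (both MH products zero) are dropped
  degen <- two_by_two(0, 5, 0, 7)
  expect_warning(both <- mantel_haenszel(list(t, degen)), "dropping 1")
  expect_equal(both$n_strata, 1L)
  expect_error(suppressWarnings(mantel_haenszel(list(degen))), "degenerate")
})

test_that("saturated interaction model recovers closed-form log-odds contrasts", {
  # balanced 2x2x2 world with exact cell probabilities (dosage 0/1)
  p <- c(p00 = 0.10, p10 = 0.25, p01 = 0.15, p11 = 0.40)
  cell <- function(carrier, dosage, pr, n = 400) {
    n_case <- round(n * pr)
    data.frame(case = rep(c(1, 0), c(n_case, n - n_case)),
               carrier = carrier, dosage = dosage)
  }
  dat <- rbind(cell(0, 0, p["p00"]), cell(1, 0, p["p10"]),
               cell(0, 1, p["p01"]), cell(1, 1, p["p11"]))
  res <- fit_interaction_model(dat)
  co <- stats::setNames(res$interaction$estimate, res$interaction$term)
  lgt <- stats::qlogis
  expect_equal(unname(co["(Intercept)"]), lgt(p[["p00"]]), tolerance = 1e-6)
  expect_equal(unname(co["carrier"]), lgt(p[["p10"]]) - lgt(p[["p00"]]),
               tolerance = 1e-6)
  expect_equal(unname(co["dosage"]), lgt(p[["p01"]]) - lgt(p[["p00"]]),
               tolerance = 1e-6)
  expect_equal(unname(co["carrier:dosage"]),
               lgt(p[["p11"]]) - lgt(p[["p10"]]) - lgt(p[["p01"]]) +
                 lgt(p[["p00"]]),
               tolerance = 1e-6)
  expect_gte(res$ll_interaction, res$ll_plain)
  expect_gte(res$lrt_statistic, 0)
})

test_that("likelihood_ratio_test is definitional and validates its inputs", {
  set.seed(31)
  pop <- simulate_population(simulation_config(n_individuals = 3000, seed = 5))
  res <- fit_interaction_model(pop)
  # statistic recomputed from the two reported log-likelihoods
  expect_equal(res$lrt_statistic,
               max(0, 2 * (res$ll_interaction - res$ll_plain)),
               tolerance = 1e-12)
  # a model against itself: statistic 0, p 1
  self <- likelihood_ratio_test(res$fits$plain, res$fits$plain)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # differing record counts refused
  pop2 <- pop[1:2999, ]
  fit2 <- stats::glm(case ~ carrier + dosage, stats::binomial(), pop2)
  expect_error(likelihood_ratio_test(fit2, res$fits$interaction),
               "differing record counts")
})

test_that("complete separation and missing columns are flagged by name", {
  n <- 200
  dat <- data.frame(carrier = rep(c(0, 1), each = n / 2),
                    dosage = rep(c(0, 1, 2, 0), n / 4))
  dat$case <- dat$carrier                       # carrier separates perfectly
  expect_error(fit_interaction_model(dat), "separation.*carrier")
  expect_error(fit_interaction_model(data.frame(case = c(0, 1))),
               "missing column")
  expect_error(fit_interaction_model(data.frame(case = 1, carrier = 0:1,
                                                dosage = 0)),
               "both outcome classes")
})

test_that("null LRT p-values are uniform (KS over 500 replicates)", {
  cfg <- simulation_config(n_individuals = 2000, carrier_freq = 0.1,
                           modifier_maf = 0.3, beta0 = stats::qlogis(0.3),
                           beta_carrier = log(1.5), seed = 99L)
  set.seed(99)
  seeds <- sample.int(2^31 - 2, 500)
  p <- vapply(seeds, function(s) {
    c <- cfg; c$seed <- s
    fit_interaction_model(simulate_population(c))$lrt_p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the case-only OR converges to the interaction OR under a rare disease", {
  # information-rich configuration (common risk allele) so the seeded check
  # is sharp; independence of the loci and prevalence ~1% still hold
  for (target in c(1, 1.5, 2)) {
    cfg <- simulation_config(n_individuals = 200000, carrier_freq = 0.2,
                             modifier_maf = 0.3,
                             beta0 = stats::qlogis(0.01),
                             beta_carrier = log(2.5),
                             beta_interaction = log(target), seed = 404L)
    est <- case_only_test(sample_case_series(simulate_population(cfg)),
                          coding = "allelic")$or
    expect_equal(est, target, tolerance = 0.1)
  }
})

test_that("MH pooling agrees with a stratum-adjusted logistic model", {
  # balanced strata sharing a common carrier OR; cross-method consistency
  set.seed(2024)
  strata <- lapply(1:3, function(s) {
    n <- 4000
    carrier <- stats::rbinom(n, 1, 0.3)
    p <- stats::plogis(stats::qlogis(0.2 + 0.05 * s) + log(1.8) * carrier)
    data.frame(case = stats::rbinom(n, 1, p), carrier = carrier,
               stratum = paste0("s", s))
  })
  dat <- do.call(rbind, strata)
  tabs <- lapply(split(dat, dat$stratum), function(d) {
    two_by_two(sum(d$case & d$carrier), sum(d$case & !d$carrier),
               sum(!d$case & d$carrier), sum(!d$case & !d$carrier))
  })
  mh <- mantel_haenszel(tabs)
  fit <- stats::glm(case ~ carrier + stratum, stats::binomial(), dat)
  expect_equal(mh$pooled_or, exp(stats::coef(fit)[["carrier"]]),
               tolerance = 0.05)
})
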