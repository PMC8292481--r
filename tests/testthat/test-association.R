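test_that("allelic and dominant tables reproduce the published cross-tabs", {
  # PALB2 carrier cohort vs controls, allele counts forced by genotypes
  t <- allelic_table(genotype_counts(64, 6, 0), genotype_counts(216, 27, 3))
  expect_equal(unlist(t[c("a", "b", "c", "d")], use.names = FALSE),
               c(6, 134, 33, 459))
  t2 <- allelic_table(genotype_counts(342, 25, 0), genotype_counts(228, 27, 4))
  expect_equal(unlist(t2[c("a", "b", "c", "d")], use.names = FALSE),
               c(25, 709, 35, 483))
  t3 <- dominant_table(genotype_counts(44, 4, 0),
                       genotype_counts(1432, 232, 9))
  expect_equal(unlist(t3[c("a", "b", "c", "d")], use.names = FALSE),
               c(4, 44, 241, 1432))
  t4 <- dominant_table(genotype_counts(45, 4, 1), genotype_counts(603, 99, 3))
  expect_equal(unlist(t4[c("a", "b", "c", "d")], use.names = FALSE),
               c(5, 45, 102, 603))
  # identical groups give symmetric rows; all-hom-ref groups a zero alt column
  g <- genotype_counts(10, 5, 2)
  ts <- allelic_table(g, g)
  expect_equal(c(ts$a, ts$b), c(ts$c, ts$d))
  td <- dominant_table(genotype_counts(9, 0, 0), genotype_counts(4, 0, 0))
  expect_equal(c(td$a, td$c), c(0, 0))
  expect_error(allelic_table(genotype_counts(0, 0, 0), g), "empty")
})

test_that("sample OR and Woolf CI reproduce the published cells", {
  t <- two_by_two(6, 134, 33, 459)
  expect_equal(round(as.numeric(sample_or(t)), 3), 0.623)
  expect_equal(round(as.numeric(woolf_ci(t)), 3), c(0.256, 1.518))
  t2 <- two_by_two(25, 709, 35, 483)
  expect_equal(round(as.numeric(sample_or(t2)), 3), 0.487)
  expect_equal(round(as.numeric(woolf_ci(t2)), 3), c(0.288, 0.823))
  sym <- two_by_two(8, 17, 8, 17)
  expect_equal(as.numeric(sample_or(sym)), 1)
  # the interval widens without bound as the level approaches 1 and then
  # swallows any fixed OR
  widths <- sapply(c(0.9, 0.99, 0.999, 1 - 1e-12), function(l) {
    ci <- woolf_ci(t, level = l)
    log(ci[2] / ci[1])
  })
  expect_true(all(diff(widths) > 0))
  wide <- woolf_ci(t, level = 1 - 1e-12)
  expect_lt(wide[1], 0.05)
  expect_gt(wide[2], 5)
})

test_that("zero cells trigger the Haldane-Anscombe correction, double zeros error", {
  t <- two_by_two(0, 20, 5, 30)
  or <- sample_or(t)
  expect_true(attr(or, "correction_applied"))
  expect_equal(as.numeric(or), (0.5 * 30.5) / (20.5 * 5.5))
  expect_true(attr(woolf_ci(t), "correction_applied"))
  expect_false(attr(sample_or(two_by_two(1, 2, 3, 4)), "correction_applied"))
  expect_error(sample_or(two_by_two(0, 0, 3, 4)), "undefined")
  expect_error(sample_or(two_by_two(0, 2, 0, 4)), "undefined")
})

test_that("Pearson chi-square p-values match print without continuity correction", {
  expect_equal(round(pearson_chi2_p(two_by_two(25, 709, 35, 483)), 3), 0.006)
  expect_equal(round(pearson_chi2_p(two_by_two(19, 559, 35, 483)), 3), 0.008)
  expect_equal(pearson_chi2_p(two_by_two(6, 12, 14, 28)), 1)  # ad = bc
  expect_error(pearson_chi2_p(two_by_two(0, 0, 5, 5)), "zero margin")
})

test_that("Fisher exact p matches print and the enumeration oracle", {
  expect_equal(round(fisher_exact_p(two_by_two(2, 12, 88, 564)), 2), 1.00)
  expect_equal(fisher_exact_p(two_by_two(0, 7, 0, 9)), 1)
  # exhaustive agreement for all tables with total <= 24
  mismatches <- 0L
  for (m1 in 0:24) for (m2 in 0:(24 - m1)) for (k in 0:(m1 + m2)) {
    supp <- max(0, k - m2):min(k, m1)
    for (a in supp) {
      t <- two_by_two(a, m1 - a, k - a, m2 - (k - a))
      if (abs(fisher_exact_p(t) - enum_fisher_p(t$a, t$b, t$c, t$d)) > 1e-12) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("conditional MLE agrees with fisher.test and the grid oracle", {
  set.seed(88)
  for (i in 1:20) {
    t <- random_two_by_two(25)
    cm <- conditional_mle_or(t)
    ft <- stats::fisher.test(as.matrix(t))
    expect_equal(cm$estimate, unname(ft$estimate), tolerance = 1e-3)
    # fisher.test inverts the same tails with a coarse uniroot tolerance;
    # compare interval endpoints on the log scale
    expect_lt(abs(log(cm$ci_low) - log(ft$conf.int[1])), 0.02)
    expect_lt(abs(log(cm$ci_high) - log(ft$conf.int[2])), 0.02)
  }
  # grid-search oracle on a handful of sparse tables
  for (cells in list(c(2, 12, 88, 564), c(7, 60, 154, 549), c(1, 9, 3, 7))) {
    t <- do.call(two_by_two, as.list(cells))
    expect_equal(conditional_mle_or(t)$estimate,
                 grid_cmle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 2e-3)
  }
  # large balanced table: conditional and sample estimates within 1%
  big <- two_by_two(250, 260, 270, 255)
  expect_equal(conditional_mle_or(big)$estimate, as.numeric(sample_or(big)),
               tolerance = 0.01)
  # symmetric table
  expect_equal(conditional_mle_or(two_by_two(9, 14, 9, 14))$estimate, 1,
               tolerance = 1e-6)
  # boundary support: one-sided interval with the estimate at 0
  b <- conditional_mle_or(two_by_two(0, 10, 5, 10))
  expect_equal(b$estimate, 0)
  expect_equal(b$ci_low, 0)
  expect_gt(b$ci_high, 0)
})

test_that("row swap inverts the OR and leaves both p-values unchanged", {
  set.seed(99)
  for (i in 1:25) {
    t <- random_two_by_two()
    sw <- two_by_two(t$c, t$d, t$a, t$b)
    expect_equal(as.numeric(sample_or(sw)), 1 / as.numeric(sample_or(t)),
                 tolerance = 1e-12)
    expect_equal(pearson_chi2_p(sw), pearson_chi2_p(t), tolerance = 1e-12)
    expect_equal(fisher_exact_p(sw), fisher_exact_p(t), tolerance = 1e-9)
    # transposition invariance of the chi-square
    tr <- two_by_two(t$a, t$c, t$b, t$d)
    expect_equal(pearson_chi2_p(tr), pearson_chi2_p(t), tolerance = 1e-12)
  }
})

test_that("the Woolf interval shrinks as all cells scale up", {
  t <- two_by_two(6, 14, 9, 11)
  widths <- sapply(c(1, 2, 5, 10), function(k) {
    ci <- woolf_ci(two_by_two(6 * k, 14 * k, 9 * k, 11 * k))
    log(ci[2]) - log(ci[1])
  })
  expect_true(all(diff(widths) < 0))
})

test_that("assoc_test assembles coding, estimator, CI and test coherently", {
  g1 <- genotype_counts(64, 6, 0); g2 <- genotype_counts(216, 27, 3)
  res <- assoc_test(g1, g2, coding = "allelic")
  expect_s3_class(res, "association_result")
  expect_equal(round(res$or_estimate, 3), 0.623)
  expect_true(res$ci_low <= res$or_estimate & res$or_estimate <= res$ci_high)
  expect_false(res$correction_applied)
  ex <- assoc_test(g1, g2, estimator = "conditional_mle", ci_method = "exact",
                   test = "fisher_exact")
  expect_true(ex$ci_low <= ex$or_estimate & ex$or_estimate <= ex$ci_high)
  expect_true(ex$p_value >= 0 && ex$p_value <= 1)
  rec <- assoc_test(genotype_counts(10, 5, 4), genotype_counts(12, 6, 2),
                    coding = "recessive")
  expect_equal(rec$table$a, 4)
})
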