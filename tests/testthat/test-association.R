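test_that("calls and phenotypes build the deletion-carrier table", {
  calls <- tibble::tibble(
    sample = c("c1", "c2", "c3", "k1", "k2", "k3", "k4"),
    category = c("DELETION_B", "NORMAL", "DUPLICATION_B",
                 "DELETION_B", "DELETION_B", "NORMAL", "DUPLICATION_B"))
  phen <- tibble::tibble(sample = calls$sample,
                         status = c("case", "case", "case",
                                    "control", "control", "control",
                                    "control"),
                         stratum = "s1")
  t <- build_table(calls, phen, "s1")
  # duplications count as non-carriers
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 2, 2, 2))
  phen_bad <- phen
  phen_bad$status[1] <- "unknown"
  expect_error(build_table(calls, phen_bad, "s1"), "case")
  none <- suppressMessages(
    build_table(calls[calls$category == "NORMAL", ], phen, "s1"))
  expect_equal(none$a + none$c, 0)
})

test_that("crude odds ratios reproduce the published per-stratum values", {
  expect_equal(odds_ratio(swe_table())$or, 0.442, tolerance = 5e-3)
  expect_equal(odds_ratio(uk_table())$or, 0.533, tolerance = 5e-3)
  expect_equal(odds_ratio(us_table())$or, 0.617, tolerance = 5e-3)
  expect_equal(odds_ratio(contingency_2x2(5, 5, 5, 5))$or, 1)
  z <- odds_ratio(contingency_2x2(0, 10, 5, 10))
  expect_equal(z$or, 0)
  expect_true(z$one_sided)
  expect_error(odds_ratio(contingency_2x2(0, 10, 0, 10)), "undefined")
})

test_that("Woolf CI follows the closed form", {
  t <- swe_table()
  o <- odds_ratio(t)
  se <- sqrt(1 / 28 + 1 / 2375 + 1 / 33 + 1 / 1236)
  expect_equal(o$log_or_se, se)
  expect_equal(o$ci95, exp(log(o$or) + c(-1, 1) * qnorm(0.975) * se))
})

test_that("Pearson chi-squared matches the uncorrected oracle", {
  ch <- pearson_chi2(swe_table())
  expect_equal(ch$p, 0.0012, tolerance = 2e-2)
  oracle <- chisq.test(matrix(c(28, 2375, 33, 1236), 2, byrow = TRUE),
                       correct = FALSE)
  expect_equal(ch$chi2, unname(oracle$statistic))
  expect_equal(ch$p, oracle$p.value)
  ch_uk <- pearson_chi2(uk_table())
  oracle_uk <- chisq.test(matrix(c(9, 1837, 67, 7288), 2, byrow = TRUE),
                          correct = FALSE)
  expect_equal(ch_uk$chi2, unname(oracle_uk$statistic))
  expect_equal(ch_uk$chi2, 3.23, tolerance = 1e-2)
  eq <- pearson_chi2(contingency_2x2(10, 20, 5, 10))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  expect_error(pearson_chi2(contingency_2x2(0, 0, 5, 5)), "margin")
})

test_that("Mantel-Haenszel pooling matches the published meta-analyses", {
  single <- mantel_haenszel(list(swe_table()))
  expect_equal(single$or_mh, odds_ratio(swe_table())$or)
  repl <- mantel_haenszel(list(uk_table(), us_table()))
  expect_equal(repl$or_mh, 0.559, tolerance = 2e-3)
  expect_equal(repl$p_mh, 0.036, tolerance = 2e-2)
  expect_equal(repl$ci95_rbg, c(0.323, 0.966), tolerance = 2e-3)
  all3 <- mantel_haenszel(list(swe_table(), uk_table(), us_table()))
  expect_equal(all3$or_mh, 0.497, tolerance = 2e-3)
  expect_equal(all3$ci95_rbg, c(0.341, 0.725), tolerance = 2e-3)
  expect_equal(all3$p_mh, 0.000194, tolerance = 2e-2)
})

test_that("Mantel-Haenszel agrees with the stats package oracle", {
  arr <- array(c(28, 33, 2375, 1236,
                 9, 67, 1837, 7288,
                 11, 9, 1956, 987), dim = c(2, 2, 3))
  oracle <- mantelhaen.test(arr, correct = FALSE)
  ours <- mantel_haenszel(list(swe_table(), uk_table(), us_table()))
  expect_equal(ours$or_mh, unname(oracle$estimate))
  expect_equal(ours$chi2_mh, unname(oracle$statistic))
  expect_equal(ours$p_mh, oracle$p.value)
  expect_equal(ours$ci95_rbg, unname(oracle$conf.int), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("single-stratum MH statistic relates to Pearson by (n-1)/n exactly", {
  for (t in list(swe_table(), uk_table(), us_table(),
                 contingency_2x2(3, 7, 11, 13))) {
    m <- mantel_haenszel(list(t))
    p <- pearson_chi2(t)
    expect_equal(m$chi2_mh, p$chi2 * (t$n - 1) / t$n)
  }
})

test_that("swapping case and control rows inverts the OR and preserves chi2", {
  for (t in list(swe_table(), uk_table(), us_table())) {
    sw <- contingency_2x2(t$c, t$d, t$a, t$b)
    expect_equal(odds_ratio(sw)$or, 1 / odds_ratio(t)$or)
    expect_equal(pearson_chi2(sw)$chi2, pearson_chi2(t)$chi2)
    expect_equal(pearson_chi2(sw)$p, pearson_chi2(t)$p)
  }
})

test_that("Woolf heterogeneity matches the fixed-effect meta-analytic oracle", {
  het <- woolf_heterogeneity(list(uk_table(), us_table()))
  expect_equal(het$q, 0.065, tolerance = 2e-2)
  expect_equal(het$p, 0.80, tolerance = 2e-2)
  skip_if_not_installed("metafor")
  tabs <- list(swe_table(), uk_table(), us_table())
  fe <- metafor::rma(
    ai = sapply(tabs, `[[`, "a"), bi = sapply(tabs, `[[`, "b"),
    ci = sapply(tabs, `[[`, "c"), di = sapply(tabs, `[[`, "d"),
    measure = "OR", method = "FE")
  het3 <- woolf_heterogeneity(tabs)
  expect_equal(het3$q, fe$QE)
  expect_equal(het3$p, fe$QEp)
  expect_gt(het3$p, 0.05)
})

test_that("identical strata show zero heterogeneity; zero cells are excluded", {
  expect_equal(woolf_heterogeneity(list(swe_table(), swe_table()))$q, 0)
  expect_equal(woolf_heterogeneity(list(swe_table(), swe_table()))$p, 1)
  withzero <- list(swe_table(), uk_table(), contingency_2x2(0, 10, 2, 10))
  expect_message(h <- woolf_heterogeneity(withzero), "excluded")
  expect_equal(h$k_used, 2)
  expect_error(suppressMessages(
    woolf_heterogeneity(list(swe_table(), contingency_2x2(0, 1, 1, 1)))),
    "at least two")
})

test_that("forest table carries strata plus an MH summary row", {
  tabs <- list(swe_table(), uk_table(), us_table())
  ft <- forest_table(tabs)
  expect_equal(nrow(ft), 4)
  expect_equal(ft$label[4], "MH summary")
  expect_equal(sum(ft$weight_share[1:3]), 1)
  single <- forest_table(list(swe_table()))
  expect_equal(single$weight_share[1], 1)
  expect_error(forest_table(list()), "no strata")
})

test_that("RBG intervals cover the generating odds ratio at nominal rate", {
  # 500 cohorts at the three published stratum sizes and control carrier
  # frequencies, true deletion OR 0.442
  cfgs <- list(cohort_sim_config(2403, 1269, 33 / 1269, 55 / 1269, 0.442),
               cohort_sim_config(1846, 7355, 67 / 7355, 0.004, 0.442),
               cohort_sim_config(1967, 996, 9 / 996, 0.004, 0.442))
  covered <- vapply(seq_len(500), function(r) {
    tabs <- lapply(seq_along(cfgs), function(j) {
      cfg <- cfgs[[j]]
      cfg$seed <- 50000L + r * 10L + j
      co <- simulate_cohort(cfg, ARCH)
      carrier <- co$allele_class == "DEL_B"
      contingency_2x2(sum(carrier & co$status == "case"),
                      sum(!carrier & co$status == "case"),
                      sum(carrier & co$status == "control"),
                      sum(!carrier & co$status == "control"))
    })
    ci <- mantel_haenszel(tabs)$ci95_rbg
    ci[1] <= 0.442 && 0.442 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("single-stratum Woolf CIs cover the generating odds ratio", {
  cfg0 <- cohort_sim_config(2403, 1269, 33 / 1269, 55 / 1269, 0.442)
  covered <- vapply(seq_len(500), function(r) {
    cfg <- cfg0
    cfg$seed <- 60000L + r
    co <- simulate_cohort(cfg, ARCH)
    carrier <- co$allele_class == "DEL_B"
    t <- contingency_2x2(sum(carrier & co$status == "case"),
                         sum(!carrier & co$status == "case"),
                         sum(carrier & co$status == "control"),
                         sum(!carrier & co$status == "control"))
    ci <- odds_ratio(t)$ci95
    ci[1] <= 0.442 && 0.442 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
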