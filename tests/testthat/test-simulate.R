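test_that("odds transform reproduces the expected case carrier frequency", {
  # control odds 33/1236 with OR 0.442 implies a case deletion-carrier
  # frequency of ~1.166%, the value printed for the discovery cohort (1.17%)
  cfg <- cohort_sim_config(n_cases = 0, n_controls = 200000,
                           control_del_carrier_freq = 33 / 1269,
                           or_del = 0.442, seed = 101)
  p_case <- tandemCNV:::case_freq_from_or(33 / 1269, 0.442)
  expect_equal(p_case, 0.0117, tolerance = 0.01)
  expect_equal(p_case, (0.442 * 33 / 1236) / (1 + 0.442 * 33 / 1236))
})

test_that("simulated control carrier frequency recovers the configured value", {
  cfg <- cohort_sim_config(n_cases = 0, n_controls = 50000, seed = 102)
  co <- simulate_cohort(cfg)
  p <- cfg$control_del_carrier_freq
  se <- sqrt(p * (1 - p) / 50000)
  expect_lt(abs(mean(co$allele_class == "DEL_B") - p), 3 * se)
})

test_that("an odds ratio of 1 equalizes case and control carrier rates", {
  cfg <- cohort_sim_config(n_cases = 50000, n_controls = 50000,
                           or_del = 1, or_dup = 1, seed = 103)
  co <- simulate_cohort(cfg)
  f <- tapply(co$allele_class == "DEL_B", co$status, mean)
  p <- cfg$control_del_carrier_freq
  se <- sqrt(2 * p * (1 - p) / 50000)
  expect_lt(abs(f[["case"]] - f[["control"]]), 3 * se)
})

test_that("an empty case stratum is valid output", {
  co <- simulate_cohort(cohort_sim_config(n_cases = 0, n_controls = 10,
                                          seed = 104))
  expect_equal(nrow(co), 10)
  expect_true(all(co$status == "control"))
})

test_that("simulators are bit-identical under a fixed seed", {
  cfg <- cohort_sim_config(n_cases = 60, n_controls = 40, seed = 105)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  g1 <- simulate_gel(co1, ARCH, gel_sim_config(seed = 106))
  g2 <- simulate_gel(co1, ARCH, gel_sim_config(seed = 106))
  expect_identical(g1, g2)
  s1 <- simulate_snps(co1, config = snp_sim_config(seed = 107))
  s2 <- simulate_snps(co1, config = snp_sim_config(seed = 107))
  expect_identical(s1, s2)
})

test_that("noiseless gel intensities reproduce the expected ratio exactly", {
  co <- simulate_cohort(cohort_sim_config(n_cases = 30, n_controls = 30,
                                          control_del_carrier_freq = 0.3,
                                          control_dup_carrier_freq = 0.3,
                                          seed = 108))
  gel <- simulate_gel(co, ARCH,
                      gel_sim_config(row_effect_sd_log = 0,
                                     band_noise_sd_log = 0,
                                     relative_efficiency_B = 1, seed = 109))
  exp_ratio <- c(NORMAL = 1, DEL_B = 0.5, DUP_B = 1.5)
  expect_equal(gel$intensity_b / gel$intensity_a,
               unname(exp_ratio[co$allele_class]))
})

test_that("row effects cancel in the intensity ratio", {
  co <- simulate_cohort(cohort_sim_config(n_cases = 0, n_controls = 48,
                                          control_del_carrier_freq = 0,
                                          control_dup_carrier_freq = 0,
                                          seed = 110))
  gel <- simulate_gel(co, ARCH,
                      gel_sim_config(row_effect_sd_log = 1.5,
                                     band_noise_sd_log = 0, seed = 111))
  expect_equal(gel$intensity_b / gel$intensity_a, rep(1, 48))
})

test_that("per-class mean log2 ratios land on the copy-model expectations", {
  co <- simulate_cohort(cohort_sim_config(n_cases = 0, n_controls = 1000,
                                          control_del_carrier_freq = 0.2,
                                          control_dup_carrier_freq = 0.2,
                                          seed = 112))
  gel <- simulate_gel(co, ARCH,
                      gel_sim_config(band_noise_sd_log = 0.1, seed = 113))
  ratios <- normalize_and_ratio(gel)
  m <- tapply(ratios$log2_ratio, co$allele_class[match(ratios$sample,
                                                       co$sample)], mean)
  expect_lt(abs(m[["NORMAL"]] - 0), 0.1)
  expect_lt(abs(m[["DEL_B"]] - (-1)), 0.1)
  expect_lt(abs(m[["DUP_B"]] - log2(3 / 2)), 0.1)
})

test_that("noiseless SNP BAFs reflect regional allelic composition", {
  mk <- function(class) {
    tibble::tibble(sample = "S1", status = "control", allele_class = class,
                   crossover_offset = ifelse(class == "NORMAL", NA, AB1_X))
  }
  cfg0 <- snp_sim_config(n_snps_region = 200, n_snps_flank = 0,
                         lrr_sd = 0, baf_sd = 0, seed = 114)
  dup <- simulate_snps(mk("DUP_B"), config = cfg0)
  het_baf <- dup$baf[!dup$baf %in% c(0, 1)]
  expect_true(all(abs(het_baf - 1 / 3) < 1e-12 |
                    abs(het_baf - 2 / 3) < 1e-12))
  del <- simulate_snps(mk("DEL_B"), config = cfg0)
  expect_true(all(del$baf %in% c(0, 1)))
  nor <- simulate_snps(mk("NORMAL"), config = cfg0)
  expect_equal(mean(nor$lrr), 0)
  expect_equal(mean(del$lrr), -0.66)
})

test_that("flanking SNPs are always two-copy", {
  co <- tibble::tibble(sample = "S1", status = "control",
                       allele_class = "DEL_B", crossover_offset = AB1_X)
  snps <- simulate_snps(co, config = snp_sim_config(lrr_sd = 0, baf_sd = 0,
                                                    seed = 115))
  region <- gint(7996000, 8125000)
  fl <- snps$position < region[["start"]] | snps$position > region[["end"]]
  expect_equal(unique(snps$lrr[fl]), 0)
})

test_that("partial-PRT profiles step at the crossover", {
  x45 <- between_loci(4)
  del <- simulate_pprt(structural_allele("DEL_B", x45), ARCH, noise_sd = 0,
                       seed = 116)
  expect_equal(del$values, c(-1, -1, -1, -1, 1, 1))
  nor <- simulate_pprt(structural_allele("NORMAL"), ARCH, noise_sd = 0,
                       seed = 117)
  expect_equal(nor$values, rep(0, 6))
  dup <- simulate_pprt(structural_allele("DUP_B", x45), ARCH, noise_sd = 0,
                       seed = 118)
  s <- log2(3 / 2)
  expect_equal(dup$values, c(s, s, s, s, -s, -s))
})

test_that("simulators leave the session RNG state untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_sim_config(n_cases = 5, n_controls = 5,
                                              seed = 119)))
  expect_identical(.Random.seed, before)
})
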