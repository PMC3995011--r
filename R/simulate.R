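#' Cohort simulation settings
#'
#' Defaults reproduce the Swedish discovery cohort: 2,403 cases and 1,269
#' controls, control deletion-carrier frequency 33/1269 and duplication-carrier
#' frequency 55/1269, deletion odds ratio 0.442. The duplication odds ratio
#' default (0.889) is the value implied by the case/control duplication counts
#' of the same cohort. Carriers are heterozygous (one NORMAL allele), matching
#' the rarity of the variant alleles.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param control_del_carrier_freq,control_dup_carrier_freq Carrier
#'   proportions among controls, in `[0, 1)`.
#' @param or_del,or_dup Case/control odds ratios for carrier status.
#' @param seed Integer RNG seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_cases = 2403L, n_controls = 1269L,
                              control_del_carrier_freq = 33 / 1269,
                              control_dup_carrier_freq = 55 / 1269,
                              or_del = 0.442, or_dup = 0.889,
                              seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, or_del > 0, or_dup > 0,
            control_del_carrier_freq >= 0, control_del_carrier_freq < 1,
            control_dup_carrier_freq >= 0, control_dup_carrier_freq < 1,
            control_del_carrier_freq + control_dup_carrier_freq < 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 control_del_carrier_freq = control_del_carrier_freq,
                 control_dup_carrier_freq = control_dup_carrier_freq,
                 or_del = or_del, or_dup = or_dup, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# Case carrier probability from the control probability and the carrier OR.
case_freq_from_or <- function(p_control, or) {
  odds <- or * p_control / (1 - p_control)
  odds / (1 + odds)
}

#' Simulate a case-control cohort with true structural genotypes
#'
#' Control carrier probabilities are as configured; case probabilities are
#' obtained per variant class by the odds transform
#' `p_case = OR * odds_control / (1 + OR * odds_control)`. All carriers are
#' NORMAL/variant heterozygotes with the crossover at the AB1 block midpoint.
#'
#' @param config A [cohort_sim_config()].
#' @param arch A [repeat_architecture()]; supplies the AB1 crossover offset.
#' @return Tibble with columns `sample`, `status` ("case"/"control"),
#'   `allele_class` ("NORMAL"/"DEL_B"/"DUP_B"), `crossover_offset`
#'   (NA for NORMAL).
#' @export
simulate_cohort <- function(config, arch = default_architecture()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  p_case_del <- case_freq_from_or(config$control_del_carrier_freq,
                                  config$or_del)
  p_case_dup <- case_freq_from_or(config$control_dup_carrier_freq,
                                  config$or_dup)
  if (p_case_del + p_case_dup >= 1)
    stop("implied case carrier probabilities exceed 1; check config")
  draw <- function(n, p_del, p_dup) {
    sample(c("DEL_B", "DUP_B", "NORMAL"), size = n, replace = TRUE,
           prob = c(p_del, p_dup, 1 - p_del - p_dup))
  }
  x_ab1 <- ab1_offset(arch)
  with_seed(config$seed, {
    cls <- c(draw(config$n_cases, p_case_del, p_case_dup),
             draw(config$n_controls, config$control_del_carrier_freq,
                  config$control_dup_carrier_freq))
    n <- config$n_cases + config$n_controls
    tibble::tibble(
      sample = sprintf("S%05d", seq_len(n)),
      status = rep(c("case", "control"),
                   c(config$n_cases, config$n_controls)),
      allele_class = cls,
      crossover_offset = ifelse(cls == "NORMAL", NA_real_, x_ab1))
  })
}

# Diploid P1-target counts for a NORMAL/variant genotype given the variant
# class and crossover offset (vectorised over samples).
class_copy_numbers <- function(allele_class, crossover_offset, locus_offset) {
  before <- locus_offset < crossover_offset
  cA <- ifelse(allele_class == "NORMAL", 2L,
        ifelse(allele_class %in% c("DEL_B", "DEL_A"),
               1L + as.integer(before),
               ifelse(before, 2L, 3L)))
  cB <- ifelse(allele_class == "NORMAL", 2L,
        ifelse(allele_class %in% c("DEL_B", "DEL_A"),
               2L - as.integer(before),
               ifelse(before, 3L, 2L)))
  list(A = cA, B = cB)
}

#' Gel simulation settings
#'
#' Band intensities are multiplicative: a shared lognormal per-gel-row batch
#' effect times a lognormal per-band noise term, which the per-row median
#' normalization of the analysis removes exactly in the noiseless case.
#'
#' The default band noise (sdlog 0.04 on the natural-log scale, about 0.08 on
#' the log2-ratio scale after combining the two bands) is calibrated to the
#' measured reliability of the assay: observed misclassification rates around
#' 1 in several thousand require roughly three standard deviations between
#' the deletion cluster (log2 ratio -1) and the deletion boundary (-0.75),
#' i.e. a log2-ratio SD near 0.08.
#'
#' @param samples_per_row Samples loaded per gel row.
#' @param row_effect_sd_log SD (natural-log scale) of the shared row effect.
#' @param band_noise_sd_log SD (natural-log scale) of per-band noise.
#' @param relative_efficiency_B Systematic amplification efficiency of the B
#'   product relative to A.
#' @param n_replicates Independent replicate gels per sample.
#' @param seed Integer RNG seed.
#' @return A `gel_sim_config` list.
#' @export
gel_sim_config <- function(samples_per_row = 12L, row_effect_sd_log = 0.2,
                           band_noise_sd_log = 0.04,
                           relative_efficiency_B = 1, n_replicates = 1L,
                           seed = 1L) {
  stopifnot(samples_per_row >= 1, row_effect_sd_log >= 0,
            band_noise_sd_log >= 0, relative_efficiency_B > 0,
            n_replicates >= 1)
  structure(list(samples_per_row = as.integer(samples_per_row),
                 row_effect_sd_log = row_effect_sd_log,
                 band_noise_sd_log = band_noise_sd_log,
                 relative_efficiency_B = relative_efficiency_B,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "gel_sim_config")
}

#' Simulate P1 gel band intensities for a cohort
#'
#' For each sample and replicate, `intensity_A = base * cA * rowEffect * eA`
#' and `intensity_B = base * cB * efficiency_B * rowEffect * eB`, where
#' (cA, cB) are the diploid P1 target counts of the true genotype, the row
#' effect is lognormal and shared by all samples in a gel row (drawn afresh
#' per replicate gel), and the band noises are independent lognormal terms.
#'
#' @param cohort Tibble from [simulate_cohort()] (columns `sample`,
#'   `allele_class`, `crossover_offset`).
#' @param arch A [repeat_architecture()].
#' @param config A [gel_sim_config()].
#' @return Tibble with columns `sample`, `plate`, `row`, `replicate`,
#'   `intensity_a`, `intensity_b`.
#' @export
simulate_gel <- function(cohort, arch = default_architecture(),
                         config = gel_sim_config()) {
  stopifnot(inherits(config, "gel_sim_config"))
  p1 <- locus_by_name(arch, "P1")
  cn <- class_copy_numbers(cohort$allele_class, cohort$crossover_offset,
                           p1$offset)
  n <- nrow(cohort)
  if (n == 0L)
    return(tibble::tibble(sample = character(), plate = character(),
                          row = character(), replicate = integer(),
                          intensity_a = numeric(), intensity_b = numeric()))
  row_idx <- ceiling(seq_len(n) / config$samples_per_row)
  plate_idx <- ceiling(row_idx / 8)  # 8 rows per 96-well-style plate
  base <- 1000
  with_seed(config$seed, {
    out <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      row_eff <- exp(rnorm(max(row_idx), 0, config$row_effect_sd_log))
      eA <- exp(rnorm(n, 0, config$band_noise_sd_log))
      eB <- exp(rnorm(n, 0, config$band_noise_sd_log))
      out[[r]] <- tibble::tibble(
        sample = cohort$sample,
        plate = sprintf("plate%02d", plate_idx),
        row = sprintf("row%04d", row_idx),
        replicate = r,
        intensity_a = base * cn$A * row_eff[row_idx] * eA,
        intensity_b = base * cn$B * config$relative_efficiency_B *
          row_eff[row_idx] * eB)
    }
    dplyr::bind_rows(out)
  })
}

#' SNP intensity simulation settings
#'
#' LRR means per regional copy number default to literature-typical Illumina
#' array behaviour (about -0.66 for one copy, 0 for two, +0.40 for three).
#'
#' @param n_snps_region SNPs inside the CNV region.
#' @param n_snps_flank SNPs outside it (split between the two flanks).
#' @param lrr_mean_by_copy Named numeric `c("1" =, "2" =, "3" =)`, strictly
#'   increasing in copy number.
#' @param lrr_sd,baf_sd Gaussian noise SDs for LRR and BAF.
#' @param allele_freqs Optional per-SNP B-allele frequencies (length
#'   `n_snps_region + n_snps_flank`); drawn uniformly in `[0.2, 0.8]` when
#'   `NULL`.
#' @param seed Integer RNG seed.
#' @return A `snp_sim_config` list.
#' @export
snp_sim_config <- function(n_snps_region = 20L, n_snps_flank = 20L,
                           lrr_mean_by_copy = c("1" = -0.66, "2" = 0,
                                                "3" = 0.40),
                           lrr_sd = 0.15, baf_sd = 0.03,
                           allele_freqs = NULL, seed = 1L) {
  stopifnot(n_snps_region >= 1, n_snps_flank >= 0, lrr_sd >= 0, baf_sd >= 0,
            all(c("1", "2", "3") %in% names(lrr_mean_by_copy)),
            diff(lrr_mean_by_copy[c("1", "2", "3")]) > 0)
  if (!is.null(allele_freqs))
    stopifnot(length(allele_freqs) == n_snps_region + n_snps_flank,
              all(allele_freqs >= 0 & allele_freqs <= 1))
  structure(list(n_snps_region = as.integer(n_snps_region),
                 n_snps_flank = as.integer(n_snps_flank),
                 lrr_mean_by_copy = lrr_mean_by_copy,
                 lrr_sd = lrr_sd, baf_sd = baf_sd,
                 allele_freqs = allele_freqs, seed = as.integer(seed)),
            class = "snp_sim_config")
}

#' Simulate SNP BAF/LRR tracks over the CNV region and its flanks
#'
#' Regional copy number is 1, 2 or 3 for deletion-heterozygote, normal and
#' duplication-heterozygote samples; flanking SNPs always have two copies.
#' Each copy carries a B allele with the SNP's allele frequency; BAF is the
#' B-allele fraction plus clipped Gaussian noise, LRR the copy-number mean
#' plus Gaussian noise. No linkage disequilibrium is modelled.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param region Genomic interval `c(start, end)` of the CNV
#'   (default chr12:7,996,000-8,125,000).
#' @param config A [snp_sim_config()].
#' @param chrom Chromosome name written to the records.
#' @return Tibble with columns `sample`, `chrom`, `position`, `baf`, `lrr`.
#' @export
simulate_snps <- function(cohort, region = gint(7996000, 8125000),
                          config = snp_sim_config(), chrom = "chr12") {
  stopifnot(inherits(config, "snp_sim_config"))
  n_reg <- config$n_snps_region
  n_fl <- config$n_snps_flank
  pos_reg <- round(seq(region[["start"]], region[["end"]],
                       length.out = n_reg))
  fl_lo <- ceiling(n_fl / 2)
  fl_hi <- n_fl - fl_lo
  pos_fl <- c(if (fl_lo) round(seq(region[["start"]] - 100000,
                                   region[["start"]] - 5000,
                                   length.out = fl_lo)),
              if (fl_hi) round(seq(region[["end"]] + 5000,
                                   region[["end"]] + 100000,
                                   length.out = fl_hi)))
  pos <- c(pos_reg, pos_fl)
  in_region <- c(rep(TRUE, n_reg), rep(FALSE, n_fl))
  n_snp <- length(pos)
  cn_region <- ifelse(cohort$allele_class == "NORMAL", 2L,
               ifelse(cohort$allele_class %in% c("DEL_B", "DEL_A"), 1L, 3L))
  with_seed(config$seed, {
    freqs <- config$allele_freqs
    if (is.null(freqs)) freqs <- runif(n_snp, 0.2, 0.8)
    n_samp <- nrow(cohort)
    cn <- ifelse(rep(in_region, times = n_samp),
                 rep(cn_region, each = n_snp), 2L)
    f <- rep(freqs, times = n_samp)
    n_b <- rbinom(n_samp * n_snp, size = cn, prob = f)
    baf <- n_b / cn + rnorm(n_samp * n_snp, 0, config$baf_sd)
    baf <- pmin(pmax(baf, 0), 1)
    lrr <- config$lrr_mean_by_copy[as.character(cn)] +
      rnorm(n_samp * n_snp, 0, config$lrr_sd)
    tibble::tibble(sample = rep(cohort$sample, each = n_snp),
                   chrom = chrom,
                   position = rep(pos, times = n_samp),
                   baf = baf,
                   lrr = unname(lrr))
  })
}

#' Simulate a partial-PRT abundance profile for one structural allele
#'
#' Returns, for a NORMAL/allele heterozygote, the per-locus log2 unit-B/unit-A
#' abundance expected from the copy-ratio model plus Gaussian noise: the
#' stepped profile from which [infer_crossover()] recovers the crossover
#' interval.
#'
#' @param allele A [structural_allele()].
#' @param arch A [repeat_architecture()]; the full panel is assayed in offset
#'   order.
#' @param noise_sd Gaussian SD on the log2 scale.
#' @param seed Integer RNG seed.
#' @param sample Sample identifier carried in the profile.
#' @return A `pprt_profile` list with fields `sample`, `panel` (locus names)
#'   and `values` (log2 ratios).
#' @export
simulate_pprt <- function(allele, arch = default_architecture(),
                          noise_sd = 0, seed = 1L, sample = "S1") {
  stopifnot(inherits(allele, "structural_allele"))
  geno <- diploid_genotype(structural_allele("NORMAL"), allele)
  expect <- vapply(arch$loci,
                   function(l) expected_ratio(geno, l)$log2, numeric(1))
  with_seed(seed, {
    vals <- expect + rnorm(length(expect), 0, noise_sd)
    pprt_profile(sample, vapply(arch$loci, `[[`, "", "name"), vals)
  })
}

#' Construct a partial-PRT profile
#' @param sample Sample identifier.
#' @param panel Ordered locus names (>= 2).
#' @param values Per-locus log2 unit-B/unit-A values, finite.
#' @return A `pprt_profile` list.
#' @export
pprt_profile <- function(sample, panel, values) {
  stopifnot(length(panel) >= 2, length(values) == length(panel),
            all(is.finite(values)))
  structure(list(sample = sample, panel = as.character(panel),
                 values = as.numeric(values)),
            class = "pprt_profile")
}

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards, so simulators are reproducible without side
# effects on the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
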