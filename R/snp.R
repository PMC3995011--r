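#' SNP-intensity caller settings
#'
#' The caller reduces each sample's in-region SNPs to two features — mean LRR
#' and BAF deviation of informative (heterozygous-range) SNPs — and applies
#' thresholds to the resulting 2-D space, in which one-, two- and three-copy
#' samples form well-separated clusters. Threshold defaults are set between
#' those clusters.
#'
#' @param region CNV region interval `c(start, end)` (default
#'   chr12:7,996,000-8,125,000).
#' @param chrom Chromosome of the region.
#' @param del_lrr_max Mean LRR at or below which (with no heterozygotes) a
#'   deletion is called.
#' @param del_het_fraction_max Maximum informative-SNP fraction compatible
#'   with a single-copy region.
#' @param dup_lrr_min,dup_baf_dev_min Mean-LRR and BAF-deviation minima for a
#'   duplication call.
#' @param informative_baf_window BAF interval defining informative
#'   (putatively heterozygous) SNPs.
#' @return A `snp_caller_config` list.
#' @export
snp_caller_config <- function(region = gint(7996000, 8125000),
                              chrom = "chr12",
                              del_lrr_max = -0.30,
                              del_het_fraction_max = 0.02,
                              dup_lrr_min = 0.15,
                              dup_baf_dev_min = 0.08,
                              informative_baf_window = c(0.25, 0.75)) {
  stopifnot(del_lrr_max < 0, dup_lrr_min > 0,
            length(informative_baf_window) == 2,
            informative_baf_window[1] < informative_baf_window[2])
  structure(list(region = region, chrom = chrom, del_lrr_max = del_lrr_max,
                 del_het_fraction_max = del_het_fraction_max,
                 dup_lrr_min = dup_lrr_min,
                 dup_baf_dev_min = dup_baf_dev_min,
                 informative_baf_window = informative_baf_window),
            class = "snp_caller_config")
}

#' Summarize a sample's SNPs over the CNV region
#'
#' For the SNPs inside the configured region: `mean_lrr` is the mean LRR;
#' informative SNPs are those whose BAF falls inside the informative window;
#' `baf_deviation` is the mean absolute deviation of informative BAFs from
#' 0.5 (0 when there are none, as in a one-copy region); `het_fraction` is
#' the informative fraction of in-region SNPs.
#'
#' @param snps SNP records for any number of samples: columns `sample`,
#'   `chrom`, `position`, `baf`, `lrr`.
#' @param config A [snp_caller_config()].
#' @return Tibble with one row per sample: `sample`, `mean_lrr`,
#'   `baf_deviation`, `het_fraction`, `n_snps`. Errors if any sample has no
#'   in-region SNPs (or if none do).
#' @export
summarize_region <- function(snps, config = snp_caller_config()) {
  stopifnot(inherits(config, "snp_caller_config"),
            all(snps$baf >= 0 & snps$baf <= 1))
  w <- config$informative_baf_window
  inside <- snps$chrom == config$chrom &
    snps$position >= config$region[["start"]] &
    snps$position <= config$region[["end"]]
  missing <- setdiff(unique(snps$sample), unique(snps$sample[inside]))
  if (length(missing))
    stop("no in-region SNPs for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  snps[inside, , drop = FALSE] |>
    dplyr::mutate(.inf = .data$baf >= w[1] & .data$baf <= w[2]) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      mean_lrr = mean(.data$lrr),
      baf_deviation = ifelse(any(.data$.inf),
                             mean(abs(.data$baf[.data$.inf] - 0.5)), 0),
      het_fraction = mean(.data$.inf),
      n_snps = dplyr::n(),
      .groups = "drop")
}

#' Call the regional CNV from per-sample summaries
#'
#' Deletion is tested first (a depressed mean LRR with essentially no
#' heterozygous SNPs), then duplication (elevated mean LRR with BAF clusters
#' displaced towards 1/3 and 2/3); anything else is NORMAL. The precedence
#' order guarantees no sample receives both variant labels.
#'
#' @param summaries Tibble from [summarize_region()].
#' @param config A [snp_caller_config()].
#' @return Calls tibble: `sample`, `mean_lrr`, `baf_deviation`,
#'   `het_fraction`, `category`, `source = "SNP"`.
#' @export
call_from_summary <- function(summaries, config = snp_caller_config()) {
  stopifnot(all(summaries$n_snps > 0))
  del <- summaries$mean_lrr <= config$del_lrr_max &
    summaries$het_fraction <= config$del_het_fraction_max
  dup <- !del & summaries$mean_lrr >= config$dup_lrr_min &
    summaries$baf_deviation >= config$dup_baf_dev_min
  tibble::tibble(sample = summaries$sample,
                 mean_lrr = summaries$mean_lrr,
                 baf_deviation = summaries$baf_deviation,
                 het_fraction = summaries$het_fraction,
                 category = ifelse(del, "DELETION_B",
                            ifelse(dup, "DUPLICATION_B", "NORMAL")),
                 source = "SNP")
}

#' QC table of the two-feature cluster space
#'
#' One row per sample with the plotted coordinates (mean LRR, BAF deviation)
#' and the call, for visual assessment of cluster separation.
#'
#' @param summaries Tibble from [summarize_region()].
#' @param config A [snp_caller_config()].
#' @return Tibble `sample`, `mean_lrr`, `baf_deviation`, `call`.
#' @export
visual_qc_table <- function(summaries, config = snp_caller_config()) {
  if (nrow(summaries) == 0L)
    return(tibble::tibble(sample = character(), mean_lrr = numeric(),
                          baf_deviation = numeric(), call = character()))
  calls <- call_from_summary(summaries, config)
  tibble::tibble(sample = calls$sample, mean_lrr = calls$mean_lrr,
                 baf_deviation = calls$baf_deviation,
                 call = calls$category)
}
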