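#' Read a tab-separated table with '#' comments
#' @param path File path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Write a tab-separated table with an optional '#' comment header
#' @param x Data frame.
#' @param path File path.
#' @param comments Character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level blocks: `seed`, `assembly`, `cohort`, `gel`, `snp`,
#' `classifier`, `snp_caller`; each block's entries are passed to the
#' corresponding `*_config()` constructor, so defaults apply to anything
#' omitted. A simulation config without a seed is refused.
#'
#' @param path YAML file path.
#' @return A named list of config objects plus `seed` and `assembly`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed) && (!is.null(y$cohort) || !is.null(y$gel) ||
                          !is.null(y$snp)))
    stop("a seed is mandatory for any simulation step")
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  add_seed <- function(block) {
    if (is.null(block)) block <- list()
    if (is.null(block$seed)) block$seed <- seed
    block
  }
  list(seed = seed,
       assembly = if (is.null(y$assembly)) "GRCh37" else y$assembly,
       cohort = do.call(cohort_sim_config, add_seed(y$cohort)),
       gel = do.call(gel_sim_config, add_seed(y$gel)),
       snp = do.call(snp_sim_config, add_seed(y$snp)),
       classifier = do.call(classifier_config,
                            if (is.null(y$classifier)) list()
                            else y$classifier),
       snp_caller = do.call(snp_caller_config,
                            if (is.null(y$snp_caller)) list()
                            else y$snp_caller))
}

run_log <- function(out_dir, step, config, counts) {
  lines <- c(sprintf("step: %s", step),
             sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("package: tandemCNV %s",
                     as.character(utils::packageVersion("tandemCNV"))),
             sprintf("config_hash: %s", rlang::hash(config)),
             sprintf("%s: %s", names(counts), unlist(counts)))
  cat(paste0(lines, "\n"), file = file.path(out_dir, paste0(step, ".log")),
      sep = "")
}

#' Simulate a full synthetic dataset to disk
#'
#' Writes four TSVs to `out_dir`: `gel.tsv`, `snp.tsv`, `phenotypes.tsv`
#' (sample, status, stratum) and `truth.tsv` (the generating genotypes),
#' plus a step log. Identical configuration and seed give byte-identical
#' files.
#'
#' @param config List as returned by [read_pipeline_config()] (or assembled
#'   from the `*_config()` constructors).
#' @param out_dir Output directory (created if needed).
#' @param stratum Stratum label written to the phenotype table.
#' @param arch A [repeat_architecture()].
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, stratum = "stratum1",
                         arch = default_architecture()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$cohort, arch)
  gel <- simulate_gel(cohort, arch, config$gel)
  snps <- simulate_snps(cohort, config = config$snp)
  phen <- tibble::tibble(sample = cohort$sample, status = cohort$status,
                         stratum = stratum)
  paths <- c(gel = file.path(out_dir, "gel.tsv"),
             snp = file.path(out_dir, "snp.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_tsv_table(gel, paths["gel"], "simulated P1 gel intensities")
  write_tsv_table(snps, paths["snp"], "simulated SNP BAF/LRR records")
  write_tsv_table(phen, paths["phenotypes"], "simulated phenotypes")
  write_tsv_table(cohort, paths["truth"], "generating genotypes")
  run_log(out_dir, "simulate", config,
          list(n_samples = nrow(cohort), n_gel_records = nrow(gel),
               n_snp_records = nrow(snps)))
  invisible(paths)
}

#' Genotype samples from gel and/or SNP intensity tables
#'
#' Runs the PRT route (per-row normalization, per-replicate classification,
#' replicate voting) on the gel table and/or the two-feature BAF/LRR caller
#' on the SNP table, writing one calls TSV per source with a provenance
#' column. When both sources are available a concordance report is also
#' written.
#'
#' @param out_dir Output directory.
#' @param gel_path,snp_path Paths to the input TSVs (either may be `NULL`).
#' @param classifier A [classifier_config()].
#' @param snp_caller A [snp_caller_config()].
#' @return Named list with the calls tibbles (`prt`, `snp`) and
#'   `concordance` (or `NULL`s), invisibly.
#' @export
run_genotype <- function(out_dir, gel_path = NULL, snp_path = NULL,
                         classifier = classifier_config(),
                         snp_caller = snp_caller_config()) {
  if (is.null(gel_path) && is.null(snp_path))
    stop("no usable inputs: provide a gel and/or SNP table")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prt_calls <- snp_calls <- conc <- NULL
  if (!is.null(gel_path)) {
    ratios <- normalize_and_ratio(read_tsv_table(gel_path))
    prt_calls <- aggregate_replicates(ratios, classifier)
    write_tsv_table(prt_calls, file.path(out_dir, "calls_prt.tsv"),
                    "PRT consensus calls")
  }
  if (!is.null(snp_path)) {
    summaries <- summarize_region(read_tsv_table(snp_path), snp_caller)
    snp_calls <- call_from_summary(summaries, snp_caller)
    write_tsv_table(snp_calls, file.path(out_dir, "calls_snp.tsv"),
                    "SNP-intensity calls")
    write_tsv_table(visual_qc_table(summaries, snp_caller),
                    file.path(out_dir, "snp_qc.tsv"),
                    "two-feature cluster QC table")
  }
  if (!is.null(prt_calls) && !is.null(snp_calls)) {
    conc <- concordance(prt_calls, snp_calls)
    write_tsv_table(tibble::tibble(rate = conc$rate,
                                   n_shared = conc$n_shared),
                    file.path(out_dir, "concordance.tsv"),
                    "PRT vs SNP concordance")
  }
  run_log(out_dir, "genotype",
          list(classifier = classifier, snp_caller = snp_caller),
          list(n_prt_calls = if (is.null(prt_calls)) 0 else nrow(prt_calls),
               n_snp_calls = if (is.null(snp_calls)) 0
                             else nrow(snp_calls)))
  invisible(list(prt = prt_calls, snp = snp_calls, concordance = conc))
}

#' Infer breakpoint intervals for a table of partial-PRT profiles
#'
#' @param out_dir Output directory.
#' @param profiles_path TSV with columns `sample`, `locus`, `log2_value`.
#' @param junctions_path Optional TSV with columns `sample`, `del_junction`,
#'   `dup_junction` (logical/0-1); when present, calls are refined against
#'   the junction assays.
#' @param arch A [repeat_architecture()].
#' @return The breakpoints tibble, invisibly. Writes `breakpoints.tsv` and a
#'   BED (`breakpoints_unitA.bed`, 0-based half-open) of the unit-A
#'   intervals of variant samples.
#' @export
run_breakpoints <- function(out_dir, profiles_path, junctions_path = NULL,
                            arch = default_architecture()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- read_tsv_table(profiles_path)
  stopifnot(all(c("sample", "locus", "log2_value") %in% names(prof)))
  junc <- if (!is.null(junctions_path)) read_tsv_table(junctions_path)
  bps <- lapply(split(prof, prof$sample), function(p) {
    bp <- infer_crossover(pprt_profile(p$sample[1], p$locus, p$log2_value),
                          arch)
    if (!is.null(junc) && p$sample[1] %in% junc$sample) {
      j <- junc[junc$sample == p$sample[1], ][1, ]
      bp <- integrate_junction(
        bp, junction_result(p$sample[1], as.logical(j$del_junction),
                            as.logical(j$dup_junction)), arch)
    }
    bp
  })
  tab <- breakpoints_table(bps)
  write_tsv_table(tab, file.path(out_dir, "breakpoints.tsv"),
                  "inferred NAHR crossover intervals (1-based inclusive)")
  variant <- tab[tab$variant_type != "NONE", , drop = FALSE]
  if (nrow(variant)) {
    gr <- GenomicRanges::GRanges(
      seqnames = "chr12",
      ranges = IRanges::IRanges(start = variant$intervalA_start,
                                end = variant$intervalA_end),
      name = variant$sample)
    rtracklayer::export(gr, file.path(out_dir, "breakpoints_unitA.bed"),
                        format = "BED")
  }
  run_log(out_dir, "breakpoints", list(junctions = !is.null(junctions_path)),
          list(n_profiles = length(bps), n_variant = nrow(variant)))
  invisible(tab)
}

#' Stratified deletion-carrier association analysis
#'
#' Either supply `calls` + `phenotypes` paths (tables are built per stratum
#' from the calls), or a counts table (columns `stratum`, `a`, `b`, `c`,
#' `d`) for the counts-only mode. Writes per-stratum, meta-analysis and
#' forest-table TSVs.
#'
#' @param out_dir Output directory.
#' @param calls_path,phenotypes_path Paths to calls and phenotype TSVs.
#' @param counts_path Path to a per-stratum 2x2 counts TSV (overrides the
#'   other two).
#' @return List with `strata` (tibble), `meta`, `heterogeneity`, `forest`,
#'   invisibly.
#' @export
run_associate <- function(out_dir, calls_path = NULL, phenotypes_path = NULL,
                          counts_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(counts_path)) {
    cts <- read_tsv_table(counts_path)
    tables <- lapply(seq_len(nrow(cts)), function(i)
      contingency_2x2(cts$a[i], cts$b[i], cts$c[i], cts$d[i],
                      label = cts$stratum[i]))
  } else {
    if (is.null(calls_path) || is.null(phenotypes_path))
      stop("provide either a counts table or calls + phenotypes")
    calls <- read_tsv_table(calls_path)
    phen <- read_tsv_table(phenotypes_path)
    strata <- unique(phen$stratum)
    tables <- lapply(strata, function(s) build_table(calls, phen, s))
    empty <- vapply(tables, function(t) t$n == 0, logical(1))
    if (any(empty)) {
      message(sum(empty), " empty stratum(s) skipped")
      tables <- tables[!empty]
    }
  }
  strata_tab <- dplyr::bind_rows(lapply(tables, stratum_association))
  meta <- mantel_haenszel(tables)
  het <- if (length(tables) >= 2) woolf_heterogeneity(tables)
  forest <- forest_table(tables, meta)
  write_tsv_table(strata_tab, file.path(out_dir, "association_strata.tsv"),
                  "per-stratum deletion-carrier association")
  meta_tab <- tibble::tibble(
    or_mh = meta$or_mh, ci_low = meta$ci95_rbg[1],
    ci_high = meta$ci95_rbg[2], chi2_mh = meta$chi2_mh, p_mh = meta$p_mh,
    woolf_q = if (is.null(het)) NA_real_ else het$q,
    woolf_df = if (is.null(het)) NA_integer_ else het$df,
    woolf_p = if (is.null(het)) NA_real_ else het$p)
  write_tsv_table(meta_tab, file.path(out_dir, "association_meta.tsv"),
                  "Mantel-Haenszel meta-analysis (RBG 95% CI)")
  write_tsv_table(forest, file.path(out_dir, "forest.tsv"),
                  "forest-plot data table")
  run_log(out_dir, "associate", list(counts_only = !is.null(counts_path)),
          list(n_strata = length(tables)))
  invisible(list(strata = strata_tab, meta = meta, heterogeneity = het,
                 forest = forest))
}
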