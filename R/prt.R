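#' Classifier thresholds for the log2 P1 ratio
#'
#' Defaults are the published category boundaries: deletion below -0.75,
#' duplication above +0.45, NORMAL in between. The inequalities are strict on
#' both sides, so a value exactly at a threshold is NORMAL.
#'
#' @param del_threshold,dup_threshold Log2-ratio boundaries,
#'   `del_threshold < dup_threshold`.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(del_threshold = -0.75, dup_threshold = 0.45) {
  stopifnot(is.finite(del_threshold), is.finite(dup_threshold),
            del_threshold < dup_threshold)
  structure(list(del_threshold = del_threshold,
                 dup_threshold = dup_threshold),
            class = "classifier_config")
}

#' Normalize gel intensities per row and compute log2 ratios
#'
#' The raw ratio of each record is `intensity_b / intensity_a`. Within each
#' gel row (grouped by plate, row and replicate gel), every raw ratio is
#' multiplied by the reciprocal of the row median of raw ratios, cancelling
#' multiplicative batch effects shared along a row; normalized ratios are then
#' log2-transformed. The median over an even count is the mean of the two
#' central order statistics (the `stats::median()` default).
#'
#' Records with missing or non-positive intensities are excluded with a
#' message; a row whose records are all unusable is skipped with a warning.
#'
#' @param gel Tibble of gel records with columns `sample`, `plate`, `row`,
#'   `replicate`, `intensity_a`, `intensity_b`.
#' @return Tibble with one row per usable record: `sample`, `plate`, `row`,
#'   `replicate`, `log2_ratio`.
#' @export
normalize_and_ratio <- function(gel) {
  need <- c("sample", "plate", "row", "replicate",
            "intensity_a", "intensity_b")
  stopifnot(all(need %in% names(gel)))
  gel <- tibble::as_tibble(gel)
  usable <- is.finite(gel$intensity_a) & is.finite(gel$intensity_b) &
    gel$intensity_a > 0 & gel$intensity_b > 0
  if (any(!usable))
    message(sum(!usable), " record(s) with non-positive or missing ",
            "intensities excluded")
  bad_rows <- unique(gel[!usable, c("plate", "row", "replicate")])
  gel <- gel[usable, , drop = FALSE]
  if (nrow(bad_rows)) {
    still <- dplyr::anti_join(bad_rows,
                              gel[, c("plate", "row", "replicate")],
                              by = c("plate", "row", "replicate"))
    if (nrow(still))
      warning(nrow(still), " gel row(s) skipped: no usable records")
  }
  gel |>
    dplyr::mutate(.raw = .data$intensity_b / .data$intensity_a) |>
    dplyr::group_by(.data$plate, .data$row, .data$replicate) |>
    dplyr::mutate(log2_ratio = log2(.data$.raw / stats::median(.data$.raw))) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("sample", "plate", "row", "replicate",
                                  "log2_ratio")))
}

#' Classify log2 ratios into three CNV categories
#'
#' @param log2_ratio Numeric vector of finite normalized log2 ratios.
#' @param config A [classifier_config()].
#' @return Character vector in `{"DELETION_B", "NORMAL", "DUPLICATION_B"}`.
#'   Classification is strict: ratios exactly at a boundary are NORMAL.
#' @export
classify_ratio <- function(log2_ratio, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"),
            all(is.finite(log2_ratio)))
  ifelse(log2_ratio < config$del_threshold, "DELETION_B",
         ifelse(log2_ratio > config$dup_threshold, "DUPLICATION_B",
                "NORMAL"))
}

#' Aggregate per-replicate ratios into consensus calls
#'
#' Each replicate is classified separately, then replicates vote: the
#' majority category wins; a tie resolves conservatively to NORMAL; any
#' disagreement between replicates sets the `discordant` flag. The consensus
#' log2 ratio is the median across replicates.
#'
#' @param ratios Tibble from [normalize_and_ratio()] (columns `sample`,
#'   `log2_ratio`; one row per replicate).
#' @param config A [classifier_config()].
#' @return Calls tibble: `sample`, `log2_ratio` (median), `n_replicates`,
#'   `category`, `discordant`, `source = "PRT"`.
#' @export
aggregate_replicates <- function(ratios, config = classifier_config()) {
  ratios |>
    dplyr::mutate(.cat = classify_ratio(.data$log2_ratio, config)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      log2_ratio = stats::median(.data$log2_ratio),
      n_replicates = dplyr::n(),
      category = consensus_category(.data$.cat),
      discordant = length(unique(.data$.cat)) > 1L,
      .groups = "drop") |>
    dplyr::mutate(source = "PRT")
}

consensus_category <- function(cats) {
  tab <- sort(table(cats), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) "NORMAL" else names(tab)[1]
}

#' Deletion-threshold sensitivity sweep
#'
#' Reruns the deletion-carrier association for each candidate deletion
#' threshold: samples are reclassified, a 2x2 carrier-by-status table built,
#' and the Pearson chi-squared test applied. A grid value producing an empty
#' carrier class in both arms yields a flagged row with `NA` statistics.
#'
#' @param ratios Calls-level tibble with `sample` and `log2_ratio` (e.g. from
#'   [aggregate_replicates()]).
#' @param phenotypes Tibble with `sample` and `status` ("case"/"control").
#' @param del_threshold_grid Strictly increasing numeric grid, all below
#'   `dup_threshold`.
#' @param dup_threshold Upper boundary held fixed during the sweep.
#' @return Tibble with one row per grid value: `threshold`, `a`, `b`, `c`,
#'   `d`, `chi2`, `p`, `flagged`.
#' @export
threshold_sensitivity <- function(ratios, phenotypes, del_threshold_grid,
                                  dup_threshold = 0.45) {
  stopifnot(!is.unsorted(del_threshold_grid, strictly = TRUE),
            all(del_threshold_grid < dup_threshold))
  dat <- dplyr::inner_join(ratios[, c("sample", "log2_ratio")], phenotypes,
                           by = "sample")
  rows <- lapply(del_threshold_grid, function(thr) {
    cfg <- classifier_config(thr, dup_threshold)
    carrier <- classify_ratio(dat$log2_ratio, cfg) == "DELETION_B"
    a <- sum(carrier & dat$status == "case")
    b <- sum(!carrier & dat$status == "case")
    c_ <- sum(carrier & dat$status == "control")
    d <- sum(!carrier & dat$status == "control")
    if (a + c_ == 0L || b + d == 0L) {
      tibble::tibble(threshold = thr, a = a, b = b, c = c_, d = d,
                     chi2 = NA_real_, p = NA_real_, flagged = TRUE)
    } else {
      ct <- contingency_2x2(a, b, c_, d, label = sprintf("thr=%g", thr))
      ch <- pearson_chi2(ct)
      tibble::tibble(threshold = thr, a = a, b = b, c = c_, d = d,
                     chi2 = ch$chi2, p = ch$p, flagged = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Concordance between two call sets
#'
#' @param calls_a,calls_b Calls tibbles with `sample` and `category`.
#' @return List with `rate` (matching categories / shared samples),
#'   `n_shared`, and `crosstab` (table of category A vs category B).
#' @export
concordance <- function(calls_a, calls_b) {
  m <- dplyr::inner_join(calls_a[, c("sample", "category")],
                         calls_b[, c("sample", "category")],
                         by = "sample", suffix = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no shared samples between the two call sets")
  lv <- c("DELETION_B", "NORMAL", "DUPLICATION_B")
  list(rate = mean(m$category_a == m$category_b),
       n_shared = nrow(m),
       crosstab = table(a = factor(m$category_a, lv),
                        b = factor(m$category_b, lv)))
}

#' Histogram-ready table of log2 ratios
#'
#' Bins consensus log2 ratios for a ratio-spread plot of the kind used to fix
#' the category boundaries by inspection.
#'
#' @param ratios Calls tibble with `log2_ratio`.
#' @param binwidth Bin width on the log2 scale.
#' @return Tibble with `bin_mid` and `count`.
#' @export
ratio_histogram <- function(ratios, binwidth = 0.05) {
  br <- seq(floor(min(ratios$log2_ratio) / binwidth) * binwidth,
            ceiling(max(ratios$log2_ratio) / binwidth) * binwidth + binwidth,
            by = binwidth)
  h <- hist(ratios$log2_ratio, breaks = br, plot = FALSE)
  tibble::tibble(bin_mid = h$mids, count = h$counts)
}
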