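#' Infer the NAHR crossover interval from a partial-PRT profile
#'
#' Fits, by exhaustive search, every single-changepoint step hypothesis to
#' the ordered per-locus log2 unit-B/unit-A values: no event (all zeros), or
#' a deletion (-1 before the crossover, +1 after) or duplication (+log2(3/2)
#' before, -log2(3/2) after) with the crossover falling between loci k and
#' k+1, for every k. Expected levels come from the diploid copy-ratio model
#' for a NORMAL/variant heterozygote, so the fit is a model-based
#' classification rather than a generic changepoint estimate. The hypothesis
#' with the smallest sum of squared residuals wins; exact ties prefer no
#' event, then the crossover nearest the panel centre.
#'
#' @param profile A [pprt_profile()] (>= 2 loci, all present in `arch`).
#'   Loci may be given in either panel orientation; they are ordered by
#'   homologous offset before fitting.
#' @param arch A [repeat_architecture()].
#' @return A `breakpoint_interval` list: `sample`, `variant_type`
#'   ("DEL"/"DUP"/"NONE"), `left_locus`, `right_locus`, `intervalA`,
#'   `intervalB` (between the inner edges of the flanking targets in each
#'   unit; NULL for NONE), `sse`, and the junction-consistency fields used by
#'   [integrate_junction()].
#' @export
infer_crossover <- function(profile, arch = default_architecture()) {
  stopifnot(inherits(profile, "pprt_profile"))
  loci <- lapply(profile$panel, locus_by_name, arch = arch)
  ord <- order(vapply(loci, `[[`, numeric(1), "offset"))
  loci <- loci[ord]
  v <- profile$values[ord]
  L <- length(v)
  if (L < 2L) stop("at least two loci are required")
  step <- log2(3 / 2)
  hyps <- list(list(type = "NONE", k = NA_integer_,
                    mu = rep(0, L)))
  for (k in seq_len(L - 1L)) {
    hyps <- c(hyps,
              list(list(type = "DEL", k = k,
                        mu = c(rep(-1, k), rep(1, L - k))),
                   list(type = "DUP", k = k,
                        mu = c(rep(step, k), rep(-step, L - k)))))
  }
  sse <- vapply(hyps, function(h) sum((v - h$mu)^2), numeric(1))
  # deterministic tie-break: NONE first, then |k - centre|, preserving the
  # enumeration order beyond that
  centre <- (L + 1) / 2
  pref <- vapply(hyps, function(h) {
    if (h$type == "NONE") -1 else abs(h$k - centre)
  }, numeric(1))
  best <- order(sse, pref)[1]
  h <- hyps[[best]]
  if (h$type == "NONE") {
    return(structure(list(sample = profile$sample, variant_type = "NONE",
                          left_locus = NA_character_,
                          right_locus = NA_character_,
                          intervalA = NULL, intervalB = NULL,
                          sse = sse[best], refined = FALSE,
                          consistent = NA),
                     class = "breakpoint_interval"))
  }
  lft <- loci[[h$k]]
  rgt <- loci[[h$k + 1L]]
  structure(list(sample = profile$sample, variant_type = h$type,
                 left_locus = lft$name, right_locus = rgt$name,
                 intervalA = gint(lft$targetA[["end"]],
                                  rgt$targetA[["start"]]),
                 intervalB = gint(lft$targetB[["end"]],
                                  rgt$targetB[["start"]]),
                 sse = sse[best], refined = FALSE, consistent = NA),
            class = "breakpoint_interval")
}

#' Widths of an inferred crossover interval in both units
#'
#' The width is the distance between the inner edges of the flanking assay
#' targets (end of the left target to start of the right target), computed
#' independently in unit A and unit B.
#'
#' @param bp A `breakpoint_interval` with `variant_type` other than "NONE".
#' @param arch A [repeat_architecture()].
#' @return Named numeric `c(width_A_bp =, width_B_bp =)`.
#' @export
interval_widths <- function(bp, arch = default_architecture()) {
  if (bp$variant_type == "NONE")
    stop("no crossover interval for a NONE call")
  lft <- locus_by_name(arch, bp$left_locus)
  rgt <- locus_by_name(arch, bp$right_locus)
  c(width_A_bp = unname(rgt$targetA[["start"]] - lft$targetA[["end"]]),
    width_B_bp = unname(rgt$targetB[["start"]] - lft$targetB[["end"]]))
}

#' Junction-assay presence/absence result for one sample
#'
#' The deletion junction is detected by the AF+UR product and the duplication
#' junction by the BF+UR product; the two flags are independent.
#'
#' @param sample Sample identifier.
#' @param deletion_junction_present,duplication_junction_present Logical.
#' @return A `junction_result` list.
#' @export
junction_result <- function(sample, deletion_junction_present,
                            duplication_junction_present) {
  structure(list(sample = sample,
                 deletion_junction_present =
                   isTRUE(deletion_junction_present),
                 duplication_junction_present =
                   isTRUE(duplication_junction_present)),
            class = "junction_result")
}

#' Refine a breakpoint interval with a junction-assay result
#'
#' If the junction assay confirms the profile-based variant type (deletion
#' junction for a DEL call, duplication junction for a DUP call, neither for
#' NONE), the crossover interval is refined to the AB1 homology block in both
#' units and flagged consistent; otherwise the original interval is kept and
#' the inconsistency flagged.
#'
#' @param bp A `breakpoint_interval`.
#' @param junction A [junction_result()] for the same sample.
#' @param arch A [repeat_architecture()] supplying the AB1 intervals.
#' @return The (possibly refined) `breakpoint_interval` with `refined` and
#'   `consistent` set.
#' @export
integrate_junction <- function(bp, junction, arch = default_architecture()) {
  if (!identical(bp$sample, junction$sample))
    stop("breakpoint and junction results are for different samples")
  expected <- switch(bp$variant_type,
                     DEL = junction$deletion_junction_present,
                     DUP = junction$duplication_junction_present,
                     NONE = !junction$deletion_junction_present &&
                            !junction$duplication_junction_present)
  bp$consistent <- isTRUE(expected)
  if (bp$consistent && bp$variant_type != "NONE") {
    bp$intervalA <- arch$ab1_A
    bp$intervalB <- arch$ab1_B
    bp$refined <- TRUE
  }
  bp
}

#' Fraction of variant samples whose breakpoint is AB1-consistent
#'
#' @param bps List of `breakpoint_interval` objects after
#'   [integrate_junction()].
#' @return List with `fraction`, `percent`, `n_consistent`, `n_variant`.
#' @export
breakpoint_census <- function(bps) {
  variant <- Filter(function(b) b$variant_type != "NONE", bps)
  if (!length(variant)) stop("no variant samples in census")
  n_cons <- sum(vapply(variant, function(b) isTRUE(b$consistent),
                       logical(1)))
  list(fraction = n_cons / length(variant),
       percent = 100 * n_cons / length(variant),
       n_consistent = n_cons,
       n_variant = length(variant))
}

#' Breakpoint intervals as a tidy table
#'
#' @param bps List of `breakpoint_interval` objects.
#' @return Tibble with one row per sample and both unit intervals.
#' @export
breakpoints_table <- function(bps) {
  dplyr::bind_rows(lapply(bps, function(b) {
    tibble::tibble(
      sample = b$sample, variant_type = b$variant_type,
      left_locus = b$left_locus, right_locus = b$right_locus,
      intervalA_start = if (is.null(b$intervalA)) NA_real_
                        else b$intervalA[["start"]],
      intervalA_end = if (is.null(b$intervalA)) NA_real_
                      else b$intervalA[["end"]],
      intervalB_start = if (is.null(b$intervalB)) NA_real_
                        else b$intervalB[["start"]],
      intervalB_end = if (is.null(b$intervalB)) NA_real_
                      else b$intervalB[["end"]],
      sse = b$sse, refined = b$refined, consistent = b$consistent)
  }))
}
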