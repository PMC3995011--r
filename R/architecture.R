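#' Genomic interval helper
#'
#' Intervals are GRCh37, 1-based, inclusive throughout the package. BED files
#' (0-based half-open) are converted on import by [read_genes_bed()].
#'
#' @param start,end Integer-like scalar coordinates, `start <= end`.
#' @return A named numeric vector `c(start =, end =)`.
#' @keywords internal
#' @export
gint <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, is.finite(start), is.finite(end))
  if (start > end) stop("interval start exceeds end: [", start, ", ", end, "]")
  if (start < 1) stop("coordinates are 1-based; start must be >= 1")
  c(start = as.numeric(start), end = as.numeric(end))
}

gint_mid <- function(x) unname((x["start"] + x["end"]) / 2)
gint_width <- function(x) unname(x["end"] - x["start"] + 1)
gint_contains <- function(outer, inner) {
  inner["start"] >= outer["start"] && inner["end"] <= outer["end"]
}

#' Define one locus of the paralogue-ratio assay panel
#'
#' Each assay locus amplifies one target in repeat unit A and the homologous
#' target in repeat unit B. Because the two units differ in length, loci are
#' placed on a single homologous scale: the `offset` is the distance (bp) of
#' the A-target start from the start of unit A, and crossover positions use
#' the same scale. Only the ordering of offsets drives inference.
#'
#' @param name Locus identifier (e.g. `"P1"`, `"B5"`).
#' @param targetA,targetB Genomic intervals ([gint()]) of the amplified
#'   targets in unit A and unit B.
#' @param unitA_start Start coordinate of unit A (used to derive the offset).
#' @return An `assay_locus` list with fields `name`, `targetA`, `targetB`,
#'   `offset`.
#' @export
assay_locus <- function(name, targetA, targetB, unitA_start) {
  offset <- unname(targetA["start"] - unitA_start)
  if (offset < 0) stop("locus ", name, " A-target starts before unit A")
  structure(list(name = name, targetA = targetA, targetB = targetB,
                 offset = offset),
            class = "assay_locus")
}

#' Describe the two-unit tandem-repeat architecture
#'
#' The chr12p13.31 repeat comprises two adjacent diverged units, A (~100 kb)
#' then B (~145 kb). The architecture records both unit spans, the ordered
#' assay panel, and the AB1 homology block (the ~1.1 kb stretch where the
#' predominant European NAHR crossover occurred) in each unit's coordinates.
#'
#' @param unitA,unitB Genomic intervals of the repeat units; unit A must
#'   precede unit B without overlap.
#' @param loci List of [assay_locus()] objects; offsets must be unique and
#'   are sorted increasing.
#' @param ab1_A,ab1_B Genomic intervals of the AB1 block in unit A / unit B.
#' @return A `repeat_architecture` list.
#' @export
repeat_architecture <- function(unitA, unitB, loci, ab1_A, ab1_B) {
  if (unitA["end"] >= unitB["start"])
    stop("unit A must precede unit B with no overlap")
  offs <- vapply(loci, function(l) l$offset, numeric(1))
  if (anyDuplicated(offs)) stop("assay locus offsets must be unique")
  loci <- loci[order(offs)]
  for (l in loci) {
    if (!gint_contains(unitA, l$targetA))
      stop("locus ", l$name, " A-target outside unit A")
    if (!gint_contains(unitB, l$targetB))
      stop("locus ", l$name, " B-target outside unit B")
  }
  structure(list(unitA = unitA, unitB = unitB, loci = loci,
                 ab1_A = ab1_A, ab1_B = ab1_B),
            class = "repeat_architecture")
}

#' @export
print.repeat_architecture <- function(x, ...) {
  cat("Two-unit tandem repeat architecture (GRCh37, 1-based inclusive)\n")
  cat(sprintf("  unit A: chr12:%.0f-%.0f (%.1f kb)\n", x$unitA["start"],
              x$unitA["end"], gint_width(x$unitA) / 1000))
  cat(sprintf("  unit B: chr12:%.0f-%.0f (%.1f kb)\n", x$unitB["start"],
              x$unitB["end"], gint_width(x$unitB) / 1000))
  cat("  panel:", paste(vapply(x$loci, `[[`, "", "name"), collapse = ", "),
      "\n")
  invisible(x)
}

locus_by_name <- function(arch, name) {
  for (l in arch$loci) if (l$name == name) return(l)
  stop("no locus named ", name, " in architecture panel")
}

#' Offset of the AB1 crossover block midpoint on the homologous scale
#' @param arch A [repeat_architecture()].
#' @return Scalar offset in bp from the unit A start.
#' @export
ab1_offset <- function(arch) {
  unname(gint_mid(arch$ab1_A) - arch$unitA["start"])
}

#' Packaged default architecture of the chr12p13.31 tandem repeat
#'
#' Unit boundaries and the B5-B10 partial-PRT target positions are not
#' published; this panel is a reconstruction chosen so that (i) the published
#' P1 and AB1 coordinates fall inside the correct units, (ii) unit sizes match
#' the reported ~100 kb / ~145 kb, (iii) the inner-edge gaps between the B5
#' and B6 targets equal the reported crossover-interval widths (8.8 kb in
#' unit A, 6.1 kb in unit B), and (iv) the AB1 block lies between the B9 and
#' B10 targets, where the predominant European crossover maps.
#'
#' @return A [repeat_architecture()] with the six-locus panel
#'   P1, B5, B6, B8, B9, B10.
#' @export
default_architecture <- function() {
  a0 <- 7896000
  loci <- list(
    # P1 targets are the published assay coordinates.
    assay_locus("P1", gint(7966286, 7966484), gint(8073299, 8073582), a0),
    # B5-B10 targets reconstructed (see above).
    assay_locus("B5", gint(7975000, 7975200), gint(8100000, 8100200), a0),
    assay_locus("B6", gint(7984000, 7984200), gint(8106300, 8106500), a0),
    assay_locus("B8", gint(7990000, 7990200), gint(8115000, 8115200), a0),
    assay_locus("B9", gint(7994500, 7994700), gint(8122000, 8122200), a0),
    assay_locus("B10", gint(7996900, 7997100), gint(8125600, 8125800), a0))
  repeat_architecture(
    unitA = gint(a0, 7997500),
    unitB = gint(7997501, 8142500),
    loci = loci,
    ab1_A = gint(7995630, 7996700),
    ab1_B = gint(8124315, 8125390))
}
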