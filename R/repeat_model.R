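#' Structural alleles of the tandem repeat
#'
#' A haplotype either carries the normal two-unit arrangement (`NORMAL`), a
#' single hybrid unit produced by NAHR-mediated unit deletion (`DEL_B`,
#' `DEL_A`), or three units produced by the reciprocal duplication (`DUP_B`,
#' `DUP_A`). The B/A suffix records which P1 target the rearrangement spans:
#' a crossover downstream of the P1 offset removes/duplicates P1\[B\], one
#' upstream removes/duplicates P1\[A\].
#'
#' @param kind One of `"NORMAL"`, `"DEL_B"`, `"DUP_B"`, `"DEL_A"`, `"DUP_A"`.
#' @param crossover_offset Crossover position on the homologous offset scale
#'   (bp from unit A start); required unless `kind = "NORMAL"`.
#' @return A `structural_allele` list.
#' @export
structural_allele <- function(kind = c("NORMAL", "DEL_B", "DUP_B",
                                       "DEL_A", "DUP_A"),
                              crossover_offset = NULL) {
  kind <- match.arg(kind)
  if (kind == "NORMAL") {
    if (!is.null(crossover_offset))
      stop("a NORMAL allele has no crossover offset")
  } else {
    if (is.null(crossover_offset) || !is.finite(crossover_offset) ||
        crossover_offset <= 0)
      stop("variant allele requires a positive crossover_offset")
  }
  structure(list(kind = kind,
                 crossover_offset = if (is.null(crossover_offset)) NA_real_
                                    else as.numeric(crossover_offset)),
            class = "structural_allele")
}

is_normal_allele <- function(a) a$kind == "NORMAL"

#' Diploid structural genotype
#'
#' The classification logic downstream assumes at least one allele is NORMAL
#' (variant alleles are rare, so compound variant genotypes are vanishingly
#' unlikely). A genotype violating that assumption is permitted, e.g. for
#' simulation studies, but flagged.
#'
#' @param allele1,allele2 [structural_allele()] objects.
#' @return A `diploid_genotype` list with a `nonstandard` flag set when
#'   neither allele is NORMAL.
#' @export
diploid_genotype <- function(allele1, allele2) {
  stopifnot(inherits(allele1, "structural_allele"),
            inherits(allele2, "structural_allele"))
  nonstandard <- !is_normal_allele(allele1) && !is_normal_allele(allele2)
  if (nonstandard)
    warning("neither allele is NORMAL; genotype flagged nonstandard")
  structure(list(allele1 = allele1, allele2 = allele2,
                 nonstandard = nonstandard),
            class = "diploid_genotype")
}

# Per-allele (A-form, B-form) copy contribution at a homologous offset.
# The deletion chromosome is a single hybrid unit A[..x]+B[x..]: loci before
# the crossover keep only their A-form, loci after it only their B-form. The
# reciprocal duplication (A + B[..x]+A[x..] + B) carries an extra B-form
# before the crossover and an extra A-form after it.
allele_copy_contribution <- function(allele, offset) {
  if (is_normal_allele(allele)) return(c(A = 1, B = 1))
  x <- allele$crossover_offset
  if (offset == x)
    stop("locus offset coincides with a crossover offset; copy number ",
         "undefined at this locus")
  del <- allele$kind %in% c("DEL_B", "DEL_A")
  if (del) {
    if (offset < x) c(A = 1, B = 0) else c(A = 0, B = 1)
  } else {
    if (offset < x) c(A = 1, B = 2) else c(A = 2, B = 1)
  }
}

#' Expected paralogue copy numbers at an assay locus
#'
#' Sums the per-allele contributions of the two structural alleles: each
#' NORMAL allele contributes one A-form and one B-form target; hybrid and
#' triplicated alleles contribute according to the side of the crossover the
#' locus falls on.
#'
#' @param genotype A [diploid_genotype()].
#' @param locus An [assay_locus()].
#' @return Named integer vector `c(A =, B =)` of diploid target counts.
#' @export
copy_numbers <- function(genotype, locus) {
  stopifnot(inherits(genotype, "diploid_genotype"),
            inherits(locus, "assay_locus"))
  allele_copy_contribution(genotype$allele1, locus$offset) +
    allele_copy_contribution(genotype$allele2, locus$offset)
}

#' Expected assay ratio B-form/A-form for a genotype at a locus
#'
#' @inheritParams copy_numbers
#' @return List with `ratio` (B count / A count) and `log2` of that ratio.
#'   A genotype with two intact chromosomes gives exactly 1 (log2 0).
#' @export
expected_ratio <- function(genotype, locus) {
  cn <- copy_numbers(genotype, locus)
  if (cn["A"] == 0)
    stop("A-form count is zero at locus ", locus$name,
         " for alleles (", genotype$allele1$kind, "/",
         genotype$allele2$kind, "); ratio undefined")
  r <- unname(cn["B"] / cn["A"])
  list(ratio = r, log2 = log2(r))
}

#' Genomic span deleted or duplicated by a crossover
#'
#' A NAHR crossover joining position x in unit A to the homologous position
#' in unit B removes (deletion product) or doubles (reciprocal duplication)
#' the sequence between the two positions. Crossovers are known only to
#' bounding intervals, so the span is computed between interval midpoints and
#' the interval half-widths are carried as uncertainty.
#'
#' @param arch A [repeat_architecture()].
#' @param crossA,crossB Crossover bounding intervals ([gint()]) in unit A and
#'   unit B respectively.
#' @return List with `interval` (midpoint-to-midpoint, c(start, end)),
#'   `length_bp`, `length_kb` (rounded to the nearest integer), and
#'   `uncertainty_bp` (half-widths of the two bounding intervals).
#' @export
rearrangement_span <- function(arch, crossA, crossB) {
  if (!gint_contains(arch$unitA, crossA))
    stop("crossA interval not inside unit A")
  if (!gint_contains(arch$unitB, crossB))
    stop("crossB interval not inside unit B")
  mA <- gint_mid(crossA)
  mB <- gint_mid(crossB)
  if (mB <= mA)
    stop("crossover midpoint in unit B must exceed that in unit A")
  len <- mB - mA
  list(interval = c(start = mA, end = mB),
       length_bp = len,
       length_kb = round(len / 1000),
       uncertainty_bp = c(A = unname(gint_width(crossA) / 2),
                          B = unname(gint_width(crossB) / 2)))
}

#' Gene consequences of a deleted/duplicated span
#'
#' @param span Genomic interval `c(start, end)` of the rearranged sequence
#'   (as returned in `rearrangement_span()$interval`).
#' @param genes A `GRanges` of gene bodies (e.g. from [read_genes_bed()])
#'   with a `name` metadata column, or a data frame with columns
#'   `name`, `start`, `end`.
#' @return A tibble with columns `gene` and `consequence`
#'   (`FULL` = gene wholly inside the span, `PARTIAL` = proper overlap,
#'   `NONE` = no overlap).
#' @export
gene_consequences <- function(span, genes) {
  if (inherits(genes, "GRanges")) {
    gdf <- tibble::tibble(name = genes$name,
                          start = GenomicRanges::start(genes),
                          end = GenomicRanges::end(genes))
  } else {
    gdf <- tibble::as_tibble(genes)[, c("name", "start", "end")]
  }
  s <- span[["start"]]; e <- span[["end"]]
  consequence <- ifelse(gdf$start >= s & gdf$end <= e, "FULL",
                 ifelse(gdf$end < s | gdf$start > e, "NONE", "PARTIAL"))
  tibble::tibble(gene = gdf$name, consequence = consequence)
}

#' Read a gene/repeat-unit BED file
#'
#' BED is 0-based half-open; import converts to the package's 1-based
#' inclusive convention. A leading comment line of the form
#' `# genome=GRCh37` (or `assembly=`) is checked against the expected
#' assembly and the file is refused on mismatch.
#'
#' @param path Path to a BED3+name file.
#' @param assembly Expected assembly tag (default `"GRCh37"`).
#' @return A `GRanges` with a `name` column.
#' @export
read_genes_bed <- function(path, assembly = "GRCh37") {
  head_lines <- readLines(path, n = 10L, warn = FALSE)
  tags <- regmatches(head_lines,
                     regexpr("(genome|assembly)=[A-Za-z0-9_.]+", head_lines))
  if (length(tags)) {
    declared <- sub("^(genome|assembly)=", "", tags[[1]])
    if (!identical(declared, assembly))
      stop("BED declares assembly ", declared, " but ", assembly,
           " expected; refusing to mix coordinate systems")
  }
  rtracklayer::import(path, format = "BED")
}
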