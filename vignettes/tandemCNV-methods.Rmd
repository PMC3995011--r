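---
title: "Models and methods behind tandemCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tandemCNV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemCNV)
```

This vignette explains the statistical models implemented in tandemCNV, the
assumptions behind them, the defaults and why they were chosen, and what the
synthetic-data generator does and does not emulate.

## The copy-ratio model of the tandem repeat

The chr12p13.31 locus carries two adjacent, highly similar repeat units, A
(~100 kb) and B (~145 kb). Because the units differ in length, the package
places every assay locus on a single *homologous offset* scale: the distance
of its unit-A target from the start of unit A. Only the ordering of offsets
matters for inference, not absolute distances, so crossovers are expressed
on the same scale.

A variant haplotype arises from one NAHR crossover joining homologous
position $x$ in the two units. The deletion chromosome is a single hybrid
unit $A[..x] + B[x..]$; loci with offset below $x$ retain only their A-form
target and loci above $x$ only their B-form. The reciprocal duplication
($A + B[..x]A[x..] + B$) carries an extra B-form below $x$ and an extra
A-form above. For a NORMAL/variant heterozygote this yields diploid B:A
counts of 2:1, 1:2, 3:2 or 2:3 and hence expected log~2~ B/A ratios of
exactly $-1$, $+1$, $+\log_2(3/2) \approx 0.585$ and $-\log_2(3/2)$; the
copy-normal ratio is exactly 0. Classification assumes at least one NORMAL
allele per individual — reasonable at carrier frequencies of a few percent,
where compound variant genotypes are vanishingly rare; the simulator can
produce them anyway, and they are flagged.

Unit boundaries and the B5–B10 partial-PRT target coordinates are not
published. The packaged `default_architecture()` reconstructs them so that
(i) the published P1 and AB1 coordinates fall inside the correct units,
(ii) unit sizes match ~100/~145 kb, (iii) the inner-edge gaps between the
B5 and B6 targets equal the reported crossover-interval widths (8.8 kb in
unit A, 6.1 kb in unit B), and (iv) the AB1 block lies between B9 and B10.
Conclusions that depend only on locus ordering are unaffected by this
reconstruction; the interval *widths* quoted for other locus pairs are
fixture properties, not measurements.

Crossovers are known only to bounding intervals, so `rearrangement_span()`
measures midpoint to midpoint and carries the interval half-widths as
uncertainty. The AB1 blocks give 128,687.5 bp, reported as 129 kb.

## PRT genotyping

Gel batch effects (DNA load, staining, electrophoresis conditions) are
multiplicative and shared along a gel row. The pipeline therefore divides
each raw ratio $I_B/I_A$ by the median raw ratio of its row — removing any
shared multiplicative term exactly — before log~2~ transformation. The
median over an even count is the mean of the central order statistics. This
normalization presumes most samples in a row are copy-normal; at the
carrier frequencies seen in these populations (2–5%) a 12-sample row
essentially never has a variant median, but users simulating high carrier
frequencies should expect row-level shifts.

Category boundaries default to the published values (deletion
$< -0.75$, duplication $> 0.45$); both inequalities are strict, so a value
exactly at a boundary is NORMAL. The boundaries were originally set by
inspection of the ratio spread; they are exposed in `classifier_config()`.
Replicates are classified individually and then vote; any disagreement sets
a `discordant` flag, and ties resolve conservatively to NORMAL rather than
to a carrier category (a laboratory would re-assay; a pipeline cannot). The
consensus ratio is the replicate median.

## The SNP-intensity caller

The published analysis used a hidden-Markov CNV caller on SNP array data
and then *validated* its calls by showing that samples separate cleanly in
the plane of mean log R ratio (LRR) versus BAF deviation of heterozygous
SNPs. tandemCNV implements that decision surface directly rather than
reimplementing the HMM: per sample, in-region SNPs are summarized by mean
LRR, the fraction of SNPs with BAF in the informative window
$[0.25, 0.75]$, and the mean $|BAF - 0.5|$ of those informative SNPs.
One-copy regions have essentially no informative SNPs (true BAF is 0 or
1), so deletions are recognized by depressed LRR plus an informative
fraction at or below 2%; three-copy regions shift heterozygote BAF to 1/3
and 2/3, so duplications need elevated LRR plus BAF deviation at or above
0.08 (the noiseless three-copy value is 1/6). Deletion is tested first, so
no sample can receive both variant labels. All thresholds are configurable
in `snp_caller_config()`; the defaults sit between the simulated cluster
centres with comfortable margins.

## Breakpoint inference

A partial-PRT panel measures the unit-B/unit-A abundance ratio at ordered
loci. A single ancestral crossover produces a step profile: $-1$ then $+1$
for a deletion, $+\log_2(3/2)$ then $-\log_2(3/2)$ for a duplication, flat
zero for no event. `infer_crossover()` enumerates all $2(L-1)+1$
hypotheses and minimizes the sum of squared residuals against these
model-derived levels — a model-based classification that is robust at the
tiny panel sizes involved ($L \le 10$), where generic changepoint
estimation would have to estimate the levels too. Exact ties prefer the
no-event hypothesis, then the crossover nearest the panel centre, making
the fit deterministic. The deletion and duplication level sets are
distinct, so the two types are never confusable on noiseless data, and the
generating hypothesis is the unique zero-residual fit.

Junction PCR assays (deletion- and duplication-specific products across
the AB1 block) refine a concordant call's interval to AB1 itself;
discordant junction results leave the interval unchanged and set an
inconsistency flag, and `breakpoint_census()` reports the AB1-consistent
fraction among variant samples.

## Association statistics

Carrier status is deletion-only: duplications count as non-carriers,
matching the replication analyses, which considered only the putative
etiological deletion. Per stratum, the crude odds ratio $ad/bc$ is reported
with a Woolf confidence interval
($\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$ on the log scale) and an
*uncorrected* Pearson $\chi^2$ test. Strata are pooled with the
Mantel–Haenszel estimator; its CI uses the Robins–Breslow–Greenland
variance, and the association test is the Mantel–Haenszel $\chi^2$ with
hypergeometric variances and no continuity correction. Woolf's test
(inverse-Woolf-variance-weighted dispersion of stratum log odds ratios)
checks the homogeneity assumption behind pooling.

Continuity corrections are deliberately absent throughout: the uncorrected
forms reproduce the published P values (0.0012, 0.036, 0.000194) exactly,
and the corrected variants do not. One bookkeeping note: the discovery
stratum's printed category counts sum to one more than its stated case
total, so case non-carriers are derived as total minus carriers
(2,403 − 28 = 2,375); only that convention reproduces the printed OR and P.
The published per-stratum CIs are wider than Woolf algebra produces
(plausibly an exact method); they are reported here as Woolf and are not
treated as reference values, whereas both published *pooled* CIs are
reproduced by the RBG interval.

## What the simulator emulates, and what it does not

`simulate_cohort()` draws carrier status per arm: controls at the
configured frequencies (defaults: the discovery-cohort values 33/1269
deletion, 55/1269 duplication), cases via the odds transform
$p = \mathrm{OR} \cdot \mathrm{odds}_{ctrl} / (1 + \mathrm{OR} \cdot
\mathrm{odds}_{ctrl})$ per variant class (default deletion OR 0.442; the
duplication default 0.889 is the value implied by the discovery-cohort
duplication counts). Carriers are heterozygous with the crossover at the
AB1 midpoint.

`simulate_gel()` models band intensities as base signal × copy number ×
lognormal row effect (shared within a row, sdlog 0.2) × lognormal band
noise. The band-noise default (sdlog 0.04, i.e. ~0.08 SD on the log~2~
ratio after combining two bands) is calibrated to the assay's measured
reliability: misclassification rates of order 1 in several thousand
require roughly three standard deviations between the deletion cluster
(−1) and the deletion boundary (−0.75). At this noise the PRT and SNP
callers agree on ~99.6–99.7% of jointly simulated samples, matching the
cross-platform concordance observed on real data (99.7%).

`simulate_snps()` draws per-SNP allelic composition binomially given the
regional copy number (1/2/3 in-region for deletion-het, normal,
duplication-het; always 2 in the flanks), with clipped Gaussian BAF noise
(default SD 0.03) and Gaussian LRR noise (default SD 0.15) around
literature-typical copy-number means (−0.66 / 0 / +0.40).

Deliberately **not** modelled: PCR saturation and allele dropout, linkage
disequilibrium between SNPs, GC waves, gel-image artefacts, multi-crossover
(gene-conversion-like) events, and alleles with more than one net unit
gained or lost. Passing simulation-based tests therefore demonstrates the
*statistical machinery* — normalization invariance, classifier geometry,
estimator calibration — not robustness to every artefact of real intensity
data.

All simulators take explicit integer seeds, restore the session RNG state
on exit, and are bit-reproducible.

## Numerical and design choices

* Coordinates are GRCh37, 1-based, inclusive everywhere; BED input/output
  (0-based half-open) is converted at the boundary by rtracklayer, and a
  BED whose header declares a different assembly is refused.
* Boundary values classify as NORMAL (strict inequalities on both sides).
* Replicate ties resolve to NORMAL; changing this to no-call would alter
  association denominators.
* The breakpoint fit prefers NONE on exact ties, then central crossovers;
  `sse` is reported so borderline fits are visible.
* Degenerate inputs: rows whose gel records are all unusable are skipped
  with a warning; samples with no in-region SNPs raise an error rather than
  silently returning an empty summary; zero-carrier tables flag undefined
  odds ratios rather than fabricating continuity-corrected ones.
* Problem sizes used by the test suite and acceptance script — 10,000
  samples for caller concordance, 1,000 replicates for breakpoint
  recovery, 500 cohorts for confidence-interval coverage — were chosen so
  that Monte-Carlo error is well below the margins being asserted while the
  whole suite runs in well under a minute.

## Known limitations

* The deletion cluster of the simulator sits at its theoretical mean of
  −1: the median normalization removes any systematic shift, whereas real
  assays showed cluster means near −1.1. Consequently, classification
  thresholds far below the cluster (e.g. −1.3) capture essentially no
  simulated deletion carriers, and a threshold-sensitivity sweep over such
  extreme values produces empty or non-significant tables by construction.
  The sweep is informative over the range in which the threshold retains
  the deletion cluster (about −0.95 and above at default noise).
* The B5–B10 panel geometry is a reconstruction (see above); interval
  widths involving those loci are fixture properties.
* The SNP caller stands in for a full HMM caller and inherits the region
  definition from configuration rather than segmenting the genome.
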