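---
title: "Rare CNV burden analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV burden analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The scientific problem

Common SNPs explain only a small part of the heritability of complex
diseases such as colorectal cancer. One candidate reservoir for the
missing part is rare copy-number variation: deletions and duplications
of >10 kb segments, each carried by well under 1% of a cohort, whose
*aggregate* load may differ between cases and controls even when no
single locus reaches significance. A burden analysis therefore compares
per-sample summary statistics — the number of rare CNVs per sample, the
fraction of samples carrying at least one, the total span in kb — between
phenotype groups, and assesses significance by permuting case/control
labels.

`cnvburden` implements that pipeline end to end for SNP-array data that
has already been segmented by two independent HMM callers (PennCNV-style
and QuantiSNP-style output): consensus calling, sample- and call-level
quality control, a dataset-internal rarity filter, genic annotation,
permutation burden testing with stratification, gene-set enrichment of
case-exclusive disrupted genes, and ΔΔCt quantification for qPCR
validation. A synthetic-cohort generator with known truth makes every
stage testable without access to any real genotype data.

## Call post-processing rules

**Coordinates.** Internally all intervals are 1-based inclusive, the
convention of the callers' region strings; `length = end − start + 1`.
BED (half-open, 0-based) and refFlat (0-based starts) are converted on
ingest. Only autosomes are analysed; sex-chromosome rows are dropped at
read time with a logged count.

**Adjacent-segment merging.** Within a sample and chromosome, two
consecutive same-state calls are merged when the gap between them is
shorter than half the total length of the pair:
`gap < 0.5 × (len1 + len2)`, with `gap = start2 − end1 − 1` and a strict
comparison. Merging is repeated left-to-right until a fixpoint,
re-evaluating the rule with the already-merged segment's length, which
makes the operation idempotent and deterministic. Overlapping same-state
calls always merge (their gap is ≤ 0); overlapping calls with different
states are rejected as inconsistent input rather than silently resolved.

**Two-caller consensus.** A call survives only if both callers report it
for the same sample with the same copy-number state and matching
breakpoints. "Matching" defaults to identity (`tolerance_bp = 0`); on a
shared probe grid both callers place boundaries on probes, so identity
is attainable, but real platforms differ and the tolerance is exposed as
a parameter rather than guessed. State identity (not merely
deletion-vs-duplication) is required; coordinates are taken from the
first caller and the Bayes factor from the QuantiSNP side, which carries
it. Merging is applied per caller *before* intersection; the reverse
order is not offered because intersecting unmerged fragments at zero
tolerance discards calls that only differ in fragmentation.

**Call-level QC.** Retained calls must be strictly longer than 10 kb,
span at least 10 probes ("ten or more" passes at exactly 10), and have a
Bayes factor strictly greater than 10; calls without a Bayes factor fail
that criterion. All three thresholds are arguments.

## Sample quality control

A sample is excluded when any of five criteria fires, each strict:
call rate < 0.95; more than 200 raw CNV calls; |GC wave factor| > 0.05;
LRR standard deviation > 0.3; QuantiSNP genome-wide LRR SD > 3.5. The
raw CNV count is each caller's own pre-consensus count (the criteria are
applied per algorithm, and a sample noisy under either caller is
excluded); post-consensus counts would hide single-caller noise. Missing
metrics exclude the sample with an explicit `missing_metric:` reason.
Ancestry outlier removal (PCA) is out of scope and can be supplied as a
pre-computed exclusion list by subsetting the sample table.

## Rarity

"Rare" is dataset-internal: a call is rare when its carrier frequency in
the pooled post-QC cohort (cases + controls) is strictly below 0.5%.
Because array CNVs have variable boundaries, carrier status between two
samples is defined by reciprocal overlap: two calls of the same type are
the same variant when each covers at least 50% of the other. Both the
fraction and the type-matching flag are configurable; the defaults are
the convention of the burden tools used for this kind of analysis. At
the reference cohort size of 2335 post-QC samples, 11 carriers
(frequency 0.47%) is rare and 12 (0.51%) is not.

## Genic annotation

Gene models are collapsed per symbol (union of transcript bounds, union
of CDS exons) before use — genic burden counts genes, not transcripts. A
call is *genic* when it overlaps any collapsed gene extended by a 10 kb
flank on each side, by at least 1 bp, with inclusive boundaries (a call
ending exactly at `tx_start − 10 kb` touches the gene). A call is
*CDS-overlapping* when it intersects a CDS exon with **no** flank: a
flank there would make the CDS class nearly identical to the genic
class and destroy its value as a stricter filter. Per-group
disrupted-gene sets are unions of hit genes over a group's rare calls,
and case-exclusive genes are the plain set difference against the
control set.

## Burden statistics and permutation inference

For a group of samples and a class filter (all / deletion / duplication
× all / genic / non-genic / CDS):

* `rate_per_sample` — calls divided by group size, zero-call samples in
  the denominator;
* `proportion_ge1` — fraction of samples with ≥ 1 matching call;
* `total_kb_per_sample` — mean over all samples of each sample's summed
  span in kb;
* `avg_kb_per_sample` — the same mean restricted to carriers.

Fold changes are ratios of unrounded group values and are reported
absent when the denominator group value is zero. Deletion and
duplication rates add up to the total rate, as do genic and non-genic.

Significance comes from label permutation holding group sizes fixed,
with the positively biased estimator `p = (r + 1)/(n_perm + 1)` so that
no empirical p is ever zero. The test is one-sided (cases > controls) by
default, matching the directional question; two-sided is available. When
`choose(n, n_cases)` ≤ 20 000 the label assignments are enumerated
exhaustively and the exact proportion is returned. Comparisons of
permuted differences with the observed one use a small relative
tolerance (1e-9) so that floating-point representation of ties cannot
flip a count. The default `n_perm` is 10 000 — desk-scale; published
analyses of this kind use 10^5–10^6, and the parameter accepts those
values.

**Stratification.** Site strata compare each tumor-site subgroup of
cases against all controls. Age tertiles are cut at the ranks
`ceiling(n/3)` and `ceiling(2n/3)` of the sorted case ages — ties at a
boundary go to the lower tertile, which makes assignment deterministic —
and comparisons run each tertile against controls plus the within-case
contrasts (T1 vs T3, T2 vs T3, T1 vs T2). Decade bins split at 50, 60,
70, 80 years. The metabolic-syndrome sensitivity analysis re-runs cases
against non-MS controls only; frequencies are *not* recomputed on that
reduced universe — rarity is always defined on whatever call set is
passed in, so a caller who wants MS-excluded frequencies simply rebuilds
the call set on that universe first.

## Gene-set enrichment

Case-exclusive disrupted genes are tested against user-supplied GMT
collections with the upper-tail hypergeometric probability; the
background defaults to all genes in the annotation. The EASE variant
subtracts one from the overlap before computing the tail, penalising
terms supported by a single gene; it is never smaller than the plain
Fisher/hypergeometric p. Bonferroni correction multiplies by the number
of terms with non-zero overlap actually tested, within each GMT
collection — enrichment databases correct per category, and the exact
historical denominators of online tools are not recoverable, so the
package documents and uses this explicit rule. No annotation database is
bundled; term membership always arrives as data.

## ΔΔCt copy number

For qPCR validation, each sample × primer pair yields
`ΔCt = mean Ct(target) − mean Ct(reference)` against an endogenous
single-copy assay (RNase P in the motivating design); `ΔΔCt` subtracts
the calibrator sample's ΔCt, the relative quantity is `2^−ΔΔCt`, and the
copy number is `2 × mean(RQ)` over primer pairs (two per region by
design). The ×2 diploid scaling and the classification cut-offs
(CN < 1.5 deletion, ≥ 2.5 duplication) are conventions of this
implementation, stated rather than inherited. Replicate spreads above
0.5 cycles flag the estimate instead of dropping it.

## The synthetic cohort generator

`simulation_config()` defaults *are* the study conditions the pipeline
targets: 694 cases vs 1641 controls, 1.39 rare CNVs per control and a
1.53-fold case excess, 55% deletions, log-normal lengths
(`meanlog = log(40 kb)`, `sdlog = 0.8`, truncated above 10 kb). Counts
are Poisson by default (published burden tables report only means, so
the count law is a modelling choice; a negative-binomial option covers
overdispersion). The synthetic genome is 22 autosomes of 10 Mb with a
1 kb probe grid: the grid is chosen so that every call above the 10 kb
length floor spans ≥ 10 probes, i.e. the length and probe-count QC
rules are distinct constraints exactly as on a real array of this
resolution. Case calls can be tilted toward gene ± 10 kb regions by a
relative-odds knob (default 1.2, a mild enrichment of the size seen in
genic-vs-total burden contrasts); controls place uniformly. Same-sample
placements are kept far enough apart that the adjacent-merge rule can
never join two distinct true calls — so the truth is stable under the
pipeline's own post-processing.

The two caller channels apply, independently: dropout (default 3%, so a
two-caller consensus retains ≈ 94% of true calls), optional breakpoint
jitter rounded to the probe grid (default 0 — on a shared grid
identical breakpoints are attainable, and non-zero jitter is for
studying the tolerance parameter), and a 5% chance of reporting a call
as two adjacent segments separated by one probe, which exercises the
merge rule end to end. Sample QC metrics are drawn inside the passing
ranges, with a configurable fraction (default 2%) given one failing
metric at random. Ages are drawn older for cases (mean 63 vs 58), so
tertiles are well-defined; an optional `age_effect` multiplier raises
young-case rates to emulate an age-dependent burden.

What the generator does **not** emulate: raw LRR/BAF intensities, the
callers' HMM error processes beyond jitter/dropout/splitting,
linkage-disequilibrium structure, recurrent CNV hotspots, or
population stratification. Passing recovery tests therefore shows the
pipeline's arithmetic and filtering are correct under the stated
generative model, not that the callers themselves are accurate on real
intensity data.

## Numerical and degenerate-input choices

* Call tables are sorted deterministically by sample, chromosome,
  start, end, state; all tie-breaks are fixed.
* Copy-number state 2 is rejected at construction: a diploid segment is
  not a CNV, and accepting it silently would corrupt type-derived
  statistics.
* Empty call sets flow through every stage (empty files read to empty
  sets; filters and annotation return empty results; burden on an empty
  group is an error rather than 0/0).
* `fold_change` with a zero denominator is reported absent (`NA`), not
  infinite.
* A constant per-sample statistic gives a permutation p of exactly 1.
* The consensus stage matches each second-caller call to at most one
  first-caller call (greedy in sorted order when tolerance > 0).
* Seeded operations save and restore the caller's RNG state, so
  library calls never perturb a user's stream.

## Problem sizes used in validation

The shipped tests validate merging against a brute-force repeated-scan
oracle on 1000 random instances, carrier counting and annotation
against all-pairs oracles, permutation calibration on 500 null
replicates at `n_perm = 999` (rejection at α = 0.05 within the binomial
band [0.03, 0.07]), enrichment against exhaustive draw enumeration on
backgrounds ≤ 15 genes, and end-to-end parameter recovery on one
cohort-scale simulation (694/1641) plus 100 null replicates at
200 vs 200. These sizes were chosen so the whole suite runs in a couple
of minutes while keeping every Monte-Carlo band at ≥ 2σ separation from
its threshold; the generator's cohort-scale defaults give the estimated
fold a sampling sd of ≈ 0.05, well inside the ±0.15 recovery band.

## Known limitations

* Rarity is dataset-internal only; no external population reference
  (DGV-style) is consulted.
* The consensus definition ("identical breakpoints") is strict by
  default and will be conservative on platforms where callers disagree
  by a probe; use `tolerance_bp` deliberately.
* DAVID-era enrichment results are not reproducible in detail because
  they depend on a historical annotation database and its gene-ID
  clustering; this package tests user-supplied gene sets with a
  documented correction rule instead.
* Cohort-specific published quantities (absolute rare-call counts,
  exclusive-gene counts, p-values) require the original genotype data
  and are out of reach of any reimplementation; what is reproducible —
  and tested — is the arithmetic that links printed totals to rates and
  fold changes, and the statistical behaviour of the machinery.
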