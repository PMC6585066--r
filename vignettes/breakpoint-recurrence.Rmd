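---
title: "Detecting recurrent copy-number breakpoint regions from SNP-array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent copy-number breakpoint regions from SNP-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cnvbreaks` implements a cohort-scale analysis of genome reorganization:
from per-SNP array intensities to segmental copy-number calls, from segment
boundaries to binned breakpoint events, and from binned events to
recurrence, tumor-specificity and fragile-site summaries. This vignette is
the package's methodological account: the model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
cohorts used in testing do and do not establish about real data.

## Signal model

The input is a matrix of per-SNP total intensities (A-allele + B-allele,
already summed or summed via `sum_alleles()`), one column per sample, keyed
to a `snp_map` of chromosome/position coordinates. A panel of non-malignant
reference arrays defines the baseline: `build_reference()` takes the
arithmetic per-SNP mean of the panel, and `log2_ratio()` expresses every
sample (reference samples included — they participate in downstream
counting as part of the non-malignant pool) as `log2(sample / reference)`.
Under the usual array model, intensity is proportional to DNA copy number
times a multiplicative noise term, so a diploid SNP sits near 0, a
one-copy gain in a diploid genome near `log2(3/2)`, and a planted doubling
at exactly +1.

SNPs with non-positive sample or reference intensity carry no ratio. They
are **masked** (dropped from segmentation, with per-sample counts recorded
and reported) rather than clamped to some floor: clamping would fabricate
extreme ratios precisely where the data are least trustworthy. No further
normalization (quantile, GC) is applied; the package assumes the intensity
extraction upstream already produced comparable arrays.

## Segmentation

`cbs_segment()` is a from-scratch implementation of circular binary
segmentation with permutation significance. Per chromosome, the statistic
is the pooled two-sample t between an arc (i, j] of the circularly joined
value sequence and its complement; circular joining lets a single scan
detect both interior "island" changes (two changepoints) and edge changes
(one). The best arc is accepted when its permutation p-value

&nbsp;&nbsp;&nbsp;&nbsp;p = (1 + #{shuffles with max |t| ≥ observed}) / (1 + B)

is ≤ α, and the resulting pieces are segmented recursively. Defaults:
α = 0.001, B = 10,000 permutations, minimum segment width 4 SNPs.

Numerical and procedural choices:

* **Piece constraint.** A candidate split must leave every resulting piece
  (arc, and the prefix/suffix parts of the complement, when non-empty) at
  least `min_width` SNPs long. This is slightly stronger than requiring it
  of arc and complement only, and guarantees by construction that every
  emitted segment satisfies the width invariant.
* **Tie-breaking.** At equal |t| the lexicographically smallest (i, j) wins,
  making results independent of scan order details.
* **Degenerate stretches.** A constant stretch has t = 0 everywhere and is
  never split; zero pooled variance with unequal means maps to t = +∞ (the
  noiseless synthetic case), which the permutation test handles unchanged.
* **Early stopping.** Permutations stop as soon as the exceedance count
  guarantees p > α (at α = 0.001, B = 10,000: after 11 exceedances). This
  changes no decision, only the work spent on clearly insignificant splits.
  Significant splits always run the full B, so the smallest attainable
  p-value is 1/(B+1); `seg_params()` warns when that exceeds α, since then
  no split could ever be accepted.
* **Determinism.** Each sample's permutation stream is seeded from the
  `seg_params()` seed and the sample's name, so a sample's segmentation does
  not depend on which other samples share the call.

After splitting, **sd-undo pruning** repeatedly merges the adjacent pair of
segments with the smallest mean difference while that difference is below
`undo_sd` (default 0.5) times the chromosome's noise SD. The noise SD is
estimated robustly as `median(|x[t+1] − x[t]|) / 0.9539` — the scaled MAD of
first differences. True copy-number shifts contribute only one large
difference each and leave the median untouched, unlike the raw SD, which
segment structure inflates; the 0.9539 factor calibrates the estimator to σ
for i.i.d. Gaussian noise (the difference of two independent N(0, σ²) draws
has median absolute value 0.9539 σ).

Equivalence with the classical DNAcopy implementation is behavioral, not
bitwise — the tests check changepoint recovery, null false-split rates and
undo behavior rather than identical output, because published CBS
implementations differ in undocumented smoothing and pruning details.

## Breakpoint calling and binning

`make_bins()` tiles each chromosome into 1-based inclusive 100 kb bins
(the terminal bin is shorter on non-multiple lengths); the male-specific and
mitochondrial chromosomes are excluded by default, as they carry too few
informative SNPs on this array class. `call_breakpoints()` emits an event
for an adjacent segment pair iff

* |mean difference| **strictly** exceeds 0.5 on the log2 scale, and
* one segment has ≥ 10 SNPs and the other ≥ 4 (symmetric in the sides).

The event is anchored at the first SNP of the downstream segment — the
"beginning of the new segment" — so one biological boundary is counted in
exactly one bin, never in both flanking bins. The delta threshold of 0.5
sits between a one-copy loss (|log2(1/2)| = 1) and a one-copy gain in a
diploid background (log2(3/2) ≈ 0.58) under perfect purity; it keeps
single-copy events of reasonable cellularity while rejecting segmentation
jitter.

## Cohort statistics

`count_by_bin()` tallies, per bin and sample group, both distinct samples
(recurrence and odds ratios use this — a sample with three events in one
bin is still one sample) and raw events (locus-level reports such as
fragile-site profiles use this). `odds_ratio()` contrasts tumor and NMCE
(non-malignant control) pools:

&nbsp;&nbsp;&nbsp;&nbsp;OR = (a / (T − a)) / (c / (N − c)),

and when either count is zero adds 0.5 **to the two numerator counts only**,
leaving the denominators at `T − a` and `N − c`. This exact variant — rather
than the textbook Haldane–Anscombe correction of all four cells — is the
disambiguation that reproduces every published two-decimal value the test
suite asserts; reciprocity (OR(a,c) · OR(c,a) = 1) and strict monotonicity
in each count hold on the uncorrected domain and are property-tested. No
multiple-testing adjustment is applied: the odds ratio here is a
descriptive ranking statistic, not an inferential one. `top_regions()`
selects bins recurrent in ≥ 20% of a cohort by default (the smallest
qualifying count for 111 samples is 23), ordering by count and breaking
ties in genome order.

`overlap_bins()` intersects bins with a fragile-site coordinate table using
inclusive-interval intersection of ≥ 1 bp (configurable); interval overlap
is delegated to `IRanges`. Site lists are consumed as coordinates (1-based
TSV or BED, converted on load); translating cytogenetic band names into
coordinates is out of scope. The fragile-site fixture shipped under
`inst/extdata/` pairs the published per-region site *assignments* with
synthetic coordinate intervals constructed to realize them, as its filename
indicates.

## Synthetic cohorts and what they show

`synthesize_cohort()` emulates the features of cohort SNP-array data this
pipeline is sensitive to: a shared SNP coordinate system, a reference panel,
group-specific planted regions whose boundaries recur with configurable
penetrance, and per-SNP multiplicative log-normal noise (additive Gaussian
on the log2 scale, the natural noise model for a log2-ratio analysis).
Expression of each region is an independent Bernoulli draw per sample;
reference samples never carry regions; planted regions may not overlap, so
the boundary truth is unambiguous. Per-sample RNG substreams are derived by
stable hashing of (seed, sample index), so enlarging a cohort leaves
existing samples' data bit-identical.

Defaults mirror a realistic design: 15 reference + 5 control arrays
(a 20-sample non-malignant pool) and 111 tumors, noise SD 0.2 on the log2
scale, baseline intensity 2000 arbitrary units. The end-to-end recovery
test plants one region (1.5 Mb, log2 shift 1.0, tumor penetrance 0.45) on a
two-chromosome genome of 10 Mb/1000 SNPs + 8 Mb/800 SNPs and checks that
exactly the two boundary bins surface in `top_regions()` with the highest
(corrected) odds ratios; test-suite segmentation runs use 1000–2000
permutations, which at α = 0.001 still leaves the minimal p-value an order
of magnitude below threshold.

What passing these tests does **not** show: robustness to wave/GC artefacts,
allele-specific signal (no BAF is simulated), tumor impurity and subclonal
fractions (penetrance is all-or-none per sample), SNP-density
inhomogeneity, or batch structure between cohorts. The generator is a
correctness harness for the pipeline's logic, not a realism benchmark.

## Reproducibility of runs

`run_pipeline()` re-validates inputs, executes all stages, and writes a
deterministic bundle: given identical inputs and configuration, every
output file is byte-identical across runs (stage timings are deliberately
reported to stderr only, and the `run_manifest.yaml` records parameters,
masked-SNP counts and input checksums, not wall-clock times). Every stage
reads the previous stage's file format, so a run can be resumed from a SEG
file and reproduces the full-run results exactly — both properties are
asserted in the test suite.

## Known limitations

* CBS here is the exact O(n²)-per-scan algorithm; tracks of many tens of
  thousands of SNPs per chromosome will be slow compared to heuristic
  implementations. The analyses this package targets bin results at 100 kb,
  so array-scale SNP densities are the intended regime.
* The odds ratio is undefined (infinite) when a cohort is saturated
  (a = T with c = 0); the uncorrected saturated case raises an error.
* Chromosome-end bins shorter than 100 kb are first-class bins; recurrence
  fractions make no length adjustment.
* The 20% recurrence threshold, 0.5 delta and 10/4 support rule are
  exposed as parameters but their defaults are treated as the method's
  definition, not tuned per dataset.
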