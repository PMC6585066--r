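# cnvbreaks

Tumor genomes do not fall apart at random: some loci are broken and
rejoined again and again, across patients and even across cancer types.
`cnvbreaks` detects such **recurrent breakpoint regions** from SNP-array
copy-number data. It takes per-SNP total allele intensities for a cohort of
samples, derives log2-ratio copy-number tracks against an averaged panel of
non-malignant reference arrays, segments each track by circular binary
segmentation (CBS), calls breakpoints between adjacent segments, assigns
them to 100 kb genome bins, and quantifies per-bin recurrence, tumor
specificity and common-fragile-site association. The intended users are
cancer-genomics analysts working with Affymetrix SNP 6.0-style intensity
matrices (or any SNP-keyed total-intensity data).

## The method in brief

For sample *s* with total intensity *x\_si* at SNP *i* and a reference panel
of *R* arrays with mean intensity *r\_i*, the copy-number signal is

> *y\_si* = log2(*x\_si* / *r\_i*).

Each chromosome's *y* sequence is partitioned by CBS: the arc (i, j] of the
circularly joined sequence maximizing the pooled two-sample |t| against its
complement is tested by permutation (p = (1 + #{perm max |t| ≥ observed}) /
(1 + B)) and accepted when p ≤ α (default α = 0.001, minimum segment width 4
SNPs); accepted pieces recurse. Adjacent segments whose means differ by less
than `undo.SD` × (robust noise SD) are then merged ("sdundo" pruning,
default 0.5).

A boundary between adjacent segments is a **breakpoint** when
|Δ mean log2| > 0.5 and one segment has ≥ 10 SNPs while the other has ≥ 4.
Each breakpoint is anchored at the first SNP of the downstream segment and
counted in its 100 kb bin. Per bin, with *a* of *T* tumor samples and *c* of
*N* non-malignant control experiments (NMCE) carrying a breakpoint, tumor
specificity is the odds ratio

> OR = (a / (T − a)) / (c / (N − c)),

with 0.5 added to both numerator counts (only) when either is zero. Bins
recurrent in ≥ 20% of a cohort are reported as common breakpoint regions and
intersected with a common-fragile-site coordinate table.

A synthetic-cohort generator (`make_snp_map()`, `cohort_config()`,
`synthesize_cohort()`) plants copy-number regions with group-specific
penetrance and records the ground-truth boundaries, so the whole pipeline is
testable end to end without array data.

## Worked example

Simulate 15 reference + 5 control + 30 tumor arrays over two chromosomes,
with one region (chrA:3,000,001–4,500,000, one extra copy, log2 shift 1.0)
planted in half of the tumors, then run the stages:

```r
library(cnvbreaks)
library(dplyr)

map <- make_snp_map(c(chrA = 1e7, chrB = 8e6),
                    c(chrA = 1000, chrB = 800), seed = 101)
cfg <- cohort_config(
  n_reference = 15,
  groups = tibble(group = c("control", "tumor"),
                  role = c("control", "tumor"), n_samples = c(5, 30)),
  planted_regions = planted_region("chrA", 3000001, 4500000,
                                   delta_log2 = 1,
                                   penetrance = c(tumor = 0.5)),
  noise_sd = 0.2, seed = 2024
)
cohort <- synthesize_cohort(map, cfg)

ref      <- build_reference(cohort$intensities,
                            with(cohort$manifest, sample_id[role == "reference"]))
ratios   <- log2_ratio(cohort$intensities, ref)
segments <- cbs_segment(ratios, seg_params(n_permutations = 2000, seed = 7))
glance(segments)
#> # A tibble: 1 × 4
#>   n_samples mean_segments_per_sample n_segments n_chroms
#>       <int>                    <dbl>      <int>    <int>
#> 1        50                     2.52        126        2

bins   <- make_bins(map$chrom_lengths)
events <- call_breakpoints(segments, bins, breakpoint_rule())
counts <- count_by_bin(events, cohort$manifest, bins)

or_table(counts) %>% arrange(desc(odds_ratio)) %>% head(4)
#> # A tibble: 4 × 8
#>   bin_id       chrom start_bp  end_bp bp_nmce bp_tumor odds_ratio corrected
#>   <chr>        <chr>    <dbl>   <dbl>   <int>    <int>      <dbl> <lgl>
#> 1 chrA:3000001 chrA   3000001 3100000       0       13     31.8   TRUE
#> 2 chrA:4500001 chrA   4500001 4600000       0       13     31.8   TRUE
#> 3 chrA:1       chrA         1  100000       0        0      0.667 TRUE
#> 4 chrA:100001  chrA    100001  200000       0        0      0.667 TRUE

top_regions(counts, "tumor", 0.20)
#> # A tibble: 2 × 6
#>   bin_id       chrom start_bp  end_bp sample_count fraction
#>   <chr>        <chr>    <dbl>   <dbl>        <int>    <dbl>
#> 1 chrA:3000001 chrA   3000001 3100000           13    0.433
#> 2 chrA:4500001 chrA   4500001 4600000           13    0.433
```

The two reported bins are exactly the planted region's boundary bins
(`truth_bins(cohort$truth, map, bins)` confirms): 13 of 30 tumors (43%)
expressed the region, no reference or control sample carries it, and the
zero NMCE cell triggers the corrected odds ratio (13.5/17) / (0.5/20) ≈ 31.8,
far above every background bin.

`run_pipeline(pipeline_config(...))` chains all stages from files on disk
and writes the full result bundle (log2 ratios, SEG segments, events, bin
counts, odds ratios, top regions, presence matrix, fragile-site summaries,
run manifest); `validate_inputs()` checks inputs beforehand. Column layouts
of every file are documented in `inst/FORMATS.md`. `plot_log2_track()`,
`autoplot()` on a segmentation, `plot_presence_matrix()` and
`plot_bin_recurrence()` draw the standard views.

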