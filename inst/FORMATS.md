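# File formats

All files are tab-separated text with a header row unless stated otherwise.
Coordinates are 1-based inclusive everywhere except BED exports. Numbers
use the decimal point, no thousands separators, independent of locale.

## Intensity / log2-ratio matrix (`intensities.tsv`, `log2_ratios.tsv`)

| column | type | notes |
|---|---|---|
| `snp_id` | string | unique |
| `chrom` | string | |
| `position` | integer bp | strictly increasing within chromosome |
| *one column per sample* | numeric | intensities ≥ 0; log2 ratios may be `NA` (masked) |

Readers/writers: `read_intensity_matrix()`, `write_intensity_matrix()`.

## Sample manifest (`manifest.tsv`)

`sample_id`, `group`, `role` (`reference`, `control`, `tumor`,
`cell_line`). A two-column file without `role` is accepted; the role then
defaults to the group name. Reader: `read_manifest()`.

## Chromosome lengths (`chrom_lengths.tsv`)

`chrom`, `length` (bp).

## Truth table (`truth.tsv`, written by `write_cohort()`)

`sample_id`, `chrom`, `boundary_bp` — one row per planted boundary
(two per expressed region: its start and its end).

## Segments, SEG-style (`segments.seg.tsv`)

`sample_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`, `mean_log2` — one row
per constant-copy-number segment; `start_bp`/`end_bp` are the positions of
the first and last member SNP. Readers/writers: `read_seg()`, `write_seg()`.

## Breakpoint events (`events.tsv`)

`sample_id`, `chrom`, `boundary_bp`, `bin_id`, `delta`, `n_left`,
`n_right`. `boundary_bp` is the first SNP of the downstream segment;
`bin_id` is `"<chrom>:<bin start>"`.

## Bin counts (`bin_counts.tsv`)

`bin_id`, `chrom`, `start_bp`, `end_bp`, `group`, `sample_count`
(distinct samples with ≥ 1 event in the bin), `event_count`.

## Odds-ratio table (`or_table.tsv`)

`bin_id`, `chrom`, `start_bp`, `end_bp`, `bp_nmce`, `bp_tumor`,
`odds_ratio`, `corrected` (`TRUE` iff a zero cell triggered the
0.5 numerator correction).

## Top regions (`top_regions.tsv`)

`bin_id`, `chrom`, `start_bp`, `end_bp`, `sample_count`, `fraction`.

## Presence matrix (`presence_matrix.tsv`)

`bin_id`, `chrom`, `start_bp`, then one 0/1 column per sample.

## Bins BED (`bins.bed`)

No header; `chrom`, `start` (0-based), `end` (half-open), `name` (= bin id).
Writer: `write_bins_bed()`.

## Fragile sites

Either a headered TSV `name`, `chrom`, `start_bp`, `end_bp` (1-based
inclusive) or 4-column BED (`chrom`, `start`, `end`, `name`; converted on
load). Reader: `read_fragile_sites()`.

The shipped `extdata/fragile_sites_synthetic.tsv` carries published site
*names and per-region assignments* with synthetic coordinate intervals
constructed to realize those assignments (cytoband-to-coordinate
translation is out of scope).

## Run manifest (`run_manifest.yaml`)

YAML: package version, all stage parameters, reference-panel size,
per-sample masked-SNP counts, md5 checksums of the inputs. No timestamps or
timings, so reruns are byte-identical.
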