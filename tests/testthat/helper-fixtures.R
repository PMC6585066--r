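# Shared fixture builders. Everything is generated in code; no binary data.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A small two-chromosome map with evenly spread SNPs (deterministic layout,
# no RNG needed).
grid_map <- function(chrom_lengths = c(chrA = 2e6, chrB = 1e6),
                     spacing = 5000) {
  snps <- purrr::imap(chrom_lengths, function(len, chr) {
    pos <- seq(spacing, len, by = spacing)
    tibble(snp_id = sprintf("%s_%05d", chr, seq_along(pos)),
           chrom = chr, position = pos)
  }) %>% bind_rows()
  snp_map(snps, chrom_lengths)
}

# One planted region at full penetrance in a small tumor group.
small_cohort <- function(noise_sd = 0, n_tumor = 3, penetrance = 1,
                         delta = 1, seed = 42) {
  map <- grid_map()
  reg <- planted_region("chrA", 500001, 900000, delta_log2 = delta,
                        penetrance = c(tumor = penetrance))
  cfg <- cohort_config(
    n_reference = 4,
    groups = tibble(group = "tumor", role = "tumor", n_samples = n_tumor),
    planted_regions = reg, noise_sd = noise_sd, seed = seed
  )
  synthesize_cohort(map, cfg)
}

# Cohort -> log2 ratios against its own reference panel.
cohort_ratios <- function(cohort) {
  ref_ids <- cohort$manifest$sample_id[cohort$manifest$role == "reference"]
  ref <- build_reference(cohort$intensities, ref_ids)
  suppressMessages(log2_ratio(cohort$intensities, ref))
}

# Random segment table for rule-equivalence oracles: per sample/chrom,
# consecutive segments with random sizes and means.
random_segments <- function(n_segments, seed) {
  withr::with_seed(seed, {
    sample_id <- sort(sample(sprintf("s%02d", 1:8), n_segments, replace = TRUE))
    rows <- list()
    for (s in unique(sample_id)) {
      k <- sum(sample_id == s)
      chrom <- sort(sample(c("chrA", "chrB"), k, replace = TRUE))
      for (chr in unique(chrom)) {
        m <- sum(chrom == chr)
        n_snps <- sample(2:30, m, replace = TRUE)
        width <- n_snps * 5000
        start <- cumsum(c(1, head(width, -1)))
        rows[[length(rows) + 1]] <- tibble(
          sample_id = s, chrom = chr,
          start_bp = start, end_bp = start + width - 1,
          n_snps = n_snps,
          mean_log2 = round(rnorm(m, 0, 0.6), 3)
        )
      }
    }
    bind_rows(rows)
  })
}

# The printed top-15 tumor recurrence table (region coordinates, NMCE and
# tumor counts, fragile-site assignment) used as a desk-scale fixture.
top15_fixture <- function() {
  readr::read_tsv(
    system.file("extdata", "top15_regions.tsv", package = "cnvbreaks"),
    show_col_types = FALSE
  )
}

top7_fixture <- function() {
  readr::read_tsv(
    system.file("extdata", "top7_ccle_regions.tsv", package = "cnvbreaks"),
    show_col_types = FALSE
  )
}

fragile_fixture_path <- function() {
  system.file("extdata", "fragile_sites_synthetic.tsv", package = "cnvbreaks")
}

# Regions table -> bins tibble (bin_id keyed like make_bins output).
regions_as_bins <- function(regions) {
  tibble(
    bin_id = sprintf("%s:%.0f", regions$chrom, regions$start_bp),
    chrom = as.character(regions$chrom),
    start_bp = regions$start_bp,
    end_bp = regions$end_bp
  )
}
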