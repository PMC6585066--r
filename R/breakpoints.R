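#' Tile chromosomes into fixed-size bins
#'
#' Splits every chromosome into consecutive bins of `bin_size` base pairs
#' (1-based inclusive); the terminal bin of a chromosome is shorter when the
#' length is not a multiple of `bin_size`. Chromosomes listed in
#' `excluded_chroms` (by default the male-specific and mitochondrial
#' chromosomes, which carry too few informative SNPs) are omitted.
#'
#' @param chrom_lengths Named numeric vector or `chrom`/`length` data frame.
#' @param bin_size Bin width in base pairs (default 100 kb).
#' @param excluded_chroms Chromosome names to drop (default
#'   `c("chrY", "Y", "chrM", "MT")`).
#' @return Tibble `bin_id` (`"<chrom>:<start_bp>"`), `chrom`, `start_bp`,
#'   `end_bp`.
#' @export
#' @examples
#' make_bins(c(chrA = 250000))
make_bins <- function(chrom_lengths, bin_size = 100000,
                      excluded_chroms = c("chrY", "Y", "chrM", "MT")) {
  if (bin_size < 1) abort("bin_size must be >= 1")
  chrom_lengths <- as_chrom_lengths(chrom_lengths) %>%
    filter(!.data$chrom %in% excluded_chroms)
  if (nrow(chrom_lengths) == 0) abort("no chromosomes left after exclusion")
  purrr::pmap(chrom_lengths, function(chrom, length) {
    k <- ceiling(length / bin_size)
    start <- (seq_len(k) - 1) * bin_size + 1
    tibble(
      bin_id = sprintf("%s:%.0f", chrom, start),
      chrom = chrom,
      start_bp = start,
      end_bp = pmin(start + bin_size - 1, length)
    )
  }) %>% bind_rows()
}

# Map (chrom, position) pairs onto bin ids; NA position -> NA bin.
assign_bin <- function(chrom, position, bins) {
  out <- rep(NA_character_, length(chrom))
  for (chr in unique(chrom)) {
    b <- bins[bins$chrom == chr, ]
    sel <- which(chrom == chr & !is.na(position))
    if (!nrow(b) || !length(sel)) next
    idx <- findInterval(position[sel], b$start_bp)
    ok <- idx >= 1 & position[sel] <= b$end_bp[pmax(idx, 1)]
    out[sel[ok]] <- b$bin_id[idx[ok]]
  }
  out
}

#' Breakpoint calling rule
#'
#' A boundary between two adjacent segments counts as a breakpoint only when
#' the segments' mean log2 ratios differ by strictly more than `min_delta`
#' and the segments are well supported: one of the two must contain at least
#' `major_min_snps` SNPs and the other at least `minor_min_snps` (the rule is
#' symmetric in the two sides).
#'
#' @param min_delta Strict lower bound on the absolute mean difference
#'   (default 0.5).
#' @param major_min_snps,minor_min_snps SNP support required of the larger /
#'   smaller segment (defaults 10 and 4).
#' @return A `breakpoint_rule` list.
#' @export
breakpoint_rule <- function(min_delta = 0.5, major_min_snps = 10,
                            minor_min_snps = 4) {
  if (min_delta <= 0) abort("min_delta must be positive")
  if (minor_min_snps < 1 || major_min_snps < minor_min_snps) {
    abort("need major_min_snps >= minor_min_snps >= 1")
  }
  structure(
    list(min_delta = min_delta,
         major_min_snps = as.integer(major_min_snps),
         minor_min_snps = as.integer(minor_min_snps)),
    class = "breakpoint_rule"
  )
}

#' Call breakpoints between adjacent segments and bin them
#'
#' Walks each sample's segments in genome order and, for every adjacent
#' same-chromosome pair passing the [breakpoint_rule()], emits one breakpoint
#' anchored at the first SNP of the downstream segment (each biological
#' boundary is counted once, in one bin).
#'
#' @param segments Segment tibble ([cbs_segment()] output or [read_seg()]).
#' @param bins Bin tibble from [make_bins()]; must cover every boundary.
#' @param rule A [breakpoint_rule()].
#' @return Tibble `sample_id`, `chrom`, `boundary_bp`, `bin_id`, `delta`,
#'   `n_left`, `n_right`.
#' @export
call_breakpoints <- function(segments, bins, rule = breakpoint_rule()) {
  stopifnot(inherits(rule, "breakpoint_rule"))
  segs <- as_tibble(segments) %>%
    filter(.data$chrom %in% unique(bins$chrom)) %>%
    arrange(.data$sample_id, .data$chrom, .data$start_bp)
  ev <- segs %>%
    group_by(.data$sample_id, .data$chrom) %>%
    mutate(
      delta = abs(.data$mean_log2 - dplyr::lag(.data$mean_log2)),
      n_left = dplyr::lag(.data$n_snps),
      n_right = .data$n_snps
    ) %>%
    ungroup() %>%
    filter(
      !is.na(.data$delta),
      .data$delta > rule$min_delta,
      pmax(.data$n_left, .data$n_right) >= rule$major_min_snps,
      pmin(.data$n_left, .data$n_right) >= rule$minor_min_snps
    ) %>%
    mutate(boundary_bp = .data$start_bp) %>%
    select("sample_id", "chrom", "boundary_bp", "delta", "n_left", "n_right")
  ev$bin_id <- assign_bin(ev$chrom, ev$boundary_bp, bins)
  if (anyNA(ev$bin_id)) {
    abort("breakpoint boundary outside all bins: chromosome lengths and data disagree")
  }
  select(ev, "sample_id", "chrom", "boundary_bp", "bin_id", "delta",
         "n_left", "n_right")
}

#' Export bins as BED
#'
#' Internal coordinates are 1-based inclusive; BED is written 0-based
#' half-open (`start_bp - 1`, `end_bp`).
#'
#' @param bins Bin tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bins_bed <- function(bins, path) {
  bed <- tibble(
    chrom = bins$chrom,
    start = format(bins$start_bp - 1, scientific = FALSE, trim = TRUE),
    end = format(bins$end_bp, scientific = FALSE, trim = TRUE),
    name = bins$bin_id
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
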