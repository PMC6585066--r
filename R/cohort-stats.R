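#' Per-bin, per-group breakpoint counts
#'
#' Tallies, for every bin and sample group, the number of distinct samples
#' with at least one breakpoint in the bin (`sample_count` — the quantity
#' recurrence and odds ratios are based on) and the total number of events
#' (`event_count`). Bins without any event are kept with zero counts so that
#' genome-wide fractions are computable.
#'
#' @param events Breakpoint tibble from [call_breakpoints()].
#' @param manifest Sample manifest (`sample_id`, `group`, `role`); defines
#'   group sizes, including samples with no events.
#' @param bins Bin tibble from [make_bins()].
#' @return A `bin_count_table` tibble: `bin_id`, `chrom`, `start_bp`,
#'   `end_bp`, `group`, `sample_count`, `event_count`; attribute
#'   `group_sizes` (named integer) and `roles` (named by group).
#' @export
count_by_bin <- function(events, manifest, bins) {
  unknown <- setdiff(unique(events$sample_id), manifest$sample_id)
  if (length(unknown)) {
    abort(paste0("events reference samples missing from manifest: ",
                 paste(unknown, collapse = ", ")))
  }
  groups <- unique(manifest$group)
  counted <- events %>%
    left_join(select(manifest, "sample_id", "group"), by = "sample_id") %>%
    group_by(.data$bin_id, .data$group) %>%
    summarise(sample_count = n_distinct(.data$sample_id),
              event_count = n(), .groups = "drop")
  out <- tidyr::expand_grid(bin_id = bins$bin_id, group = groups) %>%
    left_join(counted, by = c("bin_id", "group")) %>%
    mutate(
      sample_count = as.integer(dplyr::coalesce(.data$sample_count, 0L)),
      event_count = as.integer(dplyr::coalesce(.data$event_count, 0L))
    ) %>%
    left_join(select(bins, "bin_id", "chrom", "start_bp", "end_bp"),
              by = "bin_id") %>%
    select("bin_id", "chrom", "start_bp", "end_bp", "group",
           "sample_count", "event_count") %>%
    arrange(match(.data$bin_id, bins$bin_id), match(.data$group, groups))
  sizes <- table(factor(manifest$group, levels = groups))
  attr(out, "group_sizes") <- setNames(as.integer(sizes), names(sizes))
  attr(out, "roles") <- setNames(
    manifest$role[!duplicated(manifest$group)],
    manifest$group[!duplicated(manifest$group)]
  )
  class(out) <- c("bin_count_table", class(out))
  out
}

#' Tumor-versus-control odds ratio with zero-cell correction
#'
#' For a bin carried by `a` of `n_tumor` tumor samples and `c` of `n_nmce`
#' non-malignant control experiments (NMCE), the odds ratio is
#' `(a / (n_tumor - a)) / (c / (n_nmce - c))`. When either numerator count is
#' zero the plain formula degenerates, so 0.5 is added to both numerator
#' counts — and only to them; the denominators stay `n_tumor - a` and
#' `n_nmce - c`. Vectorized over `a` and `c`.
#'
#' @param a Tumor samples with a breakpoint in the bin.
#' @param c NMCE samples with a breakpoint in the bin.
#' @param n_tumor,n_nmce Cohort sizes.
#' @return Tibble `a`, `c`, `n_tumor`, `n_nmce`, `odds_ratio`, `corrected`.
#' @export
#' @examples
#' odds_ratio(48, 1, 111, 20)   # 14.48
#' odds_ratio(32, 0, 111, 20)   # 16.46, corrected
odds_ratio <- function(a, c, n_tumor, n_nmce) {
  k <- max(length(a), length(c))
  a <- rep_len(as.numeric(a), k)
  c <- rep_len(as.numeric(c), k)
  if (any(a < 0 | a > n_tumor) || any(c < 0 | c > n_nmce)) {
    abort("counts must lie in [0, cohort size]")
  }
  corrected <- a == 0 | c == 0
  if (any(!corrected & (a == n_tumor | c == n_nmce))) {
    abort("saturated cell (count equals cohort size): odds undefined")
  }
  num_a <- ifelse(corrected, a + 0.5, a)
  num_c <- ifelse(corrected, c + 0.5, c)
  or <- (num_a / (n_tumor - a)) / (num_c / (n_nmce - c))
  tibble(a = a, c = c, n_tumor = n_tumor, n_nmce = n_nmce,
         odds_ratio = or, corrected = corrected)
}

group_sizes_of <- function(counts) {
  gs <- attr(counts, "group_sizes")
  if (is.null(gs)) abort("count table lacks group sizes; use count_by_bin()")
  gs
}

#' Per-bin odds-ratio table
#'
#' Builds the Table-1-style report: for every bin, the NMCE and tumor
#' sample counts and their odds ratio.
#'
#' @param counts A [count_by_bin()] table.
#' @param tumor_groups,nmce_groups Group names pooled into the tumor and
#'   NMCE cohorts. Defaults: groups with role `"tumor"`, and roles
#'   `"reference"`/`"control"`, respectively.
#' @return Tibble `bin_id`, `chrom`, `start_bp`, `end_bp`, `bp_nmce`,
#'   `bp_tumor`, `odds_ratio`, `corrected`.
#' @export
or_table <- function(counts, tumor_groups = NULL, nmce_groups = NULL) {
  gs <- group_sizes_of(counts)
  roles <- attr(counts, "roles")
  if (is.null(tumor_groups)) tumor_groups <- names(roles)[roles == "tumor"]
  if (is.null(nmce_groups)) {
    nmce_groups <- names(roles)[roles %in% c("reference", "control")]
  }
  if (!length(tumor_groups) || !length(nmce_groups)) {
    abort("tumor and NMCE groups must be non-empty")
  }
  pool <- function(groups) {
    counts %>%
      filter(.data$group %in% groups) %>%
      group_by(.data$bin_id, .data$chrom, .data$start_bp, .data$end_bp) %>%
      summarise(n = sum(.data$sample_count), .groups = "drop")
  }
  tum <- pool(tumor_groups)
  nmc <- pool(nmce_groups) %>% select("bin_id", c_n = "n")
  tab <- left_join(tum, nmc, by = "bin_id")
  orv <- odds_ratio(tab$n, tab$c_n,
                    sum(gs[tumor_groups]), sum(gs[nmce_groups]))
  tab %>%
    mutate(bp_nmce = tab$c_n, bp_tumor = tab$n,
           odds_ratio = orv$odds_ratio, corrected = orv$corrected) %>%
    select("bin_id", "chrom", "start_bp", "end_bp", "bp_nmce", "bp_tumor",
           "odds_ratio", "corrected") %>%
    arrange(match(.data$bin_id, unique(counts$bin_id)))
}

#' Recurrently hit bins of a group
#'
#' Bins in which at least `fraction` of the group's samples carry a
#' breakpoint (the smallest qualifying count is `ceiling(fraction * size)`),
#' sorted by sample count descending, ties broken by genome order.
#'
#' @param counts A [count_by_bin()] table.
#' @param group Group name (or vector of names pooled together; pooled size
#'   is the sum of the group sizes).
#' @param fraction Recurrence threshold in (0, 1], default 0.20.
#' @return Tibble of qualifying bins with `sample_count` and `fraction`.
#' @export
top_regions <- function(counts, group, fraction = 0.20) {
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  gs <- group_sizes_of(counts)
  missing <- setdiff(group, names(gs))
  if (length(missing)) {
    abort(paste0("unknown group(s): ", paste(missing, collapse = ", ")))
  }
  size <- sum(gs[group])
  counts %>%
    filter(.data$group %in% !!group) %>%
    group_by(.data$bin_id, .data$chrom, .data$start_bp, .data$end_bp) %>%
    summarise(sample_count = sum(.data$sample_count), .groups = "drop") %>%
    filter(.data$sample_count / size >= fraction) %>%
    mutate(fraction = .data$sample_count / size) %>%
    arrange(dplyr::desc(.data$sample_count), .data$chrom, .data$start_bp)
}

#' Fraction of bins hit by at least one sample
#'
#' @param counts A [count_by_bin()] table.
#' @return One-row tibble `n_bins`, `n_hit`, `fraction`, `percent`
#'   (percent rounded to 2 decimals).
#' @export
#' @examples
#' # 19687 hit bins of 30951 -> 63.61%
recurrence_fraction <- function(counts) {
  if (nrow(counts) == 0) abort("empty count table")
  per_bin <- counts %>%
    group_by(.data$bin_id) %>%
    summarise(hit = sum(.data$event_count) > 0)
  n_bins <- nrow(per_bin)
  n_hit <- sum(per_bin$hit)
  tibble(
    n_bins = n_bins,
    n_hit = n_hit,
    fraction = n_hit / n_bins,
    percent = round(100 * n_hit / n_bins, 2)
  )
}

#' Breakpoint summary of a genomic interval
#'
#' Counts events whose boundary falls inside `[start_bp, end_bp]` of `chrom`
#' and the distinct samples contributing them, overall and split by group,
#' plus a per-bin sub-profile for locating hot sub-regions within a larger
#' locus (e.g. a fragile site).
#'
#' @param events Breakpoint tibble.
#' @param manifest Sample manifest.
#' @param chrom,start_bp,end_bp Query interval (1-based inclusive).
#' @return List with one-row `summary` (`event_count`, `sample_count`),
#'   `by_group` and `by_bin` tibbles.
#' @export
region_summary <- function(events, manifest, chrom, start_bp, end_bp) {
  if (start_bp > end_bp) abort("inverted interval")
  chr <- chrom
  hit <- events %>%
    filter(.data$chrom == chr,
           .data$boundary_bp >= start_bp, .data$boundary_bp <= end_bp) %>%
    left_join(select(manifest, "sample_id", "group"), by = "sample_id")
  list(
    summary = tibble(
      chrom = chr, start_bp = start_bp, end_bp = end_bp,
      event_count = nrow(hit),
      sample_count = n_distinct(hit$sample_id)
    ),
    by_group = hit %>%
      group_by(.data$group) %>%
      summarise(event_count = n(),
                sample_count = n_distinct(.data$sample_id), .groups = "drop"),
    by_bin = hit %>%
      group_by(.data$bin_id) %>%
      summarise(event_count = n(),
                sample_count = n_distinct(.data$sample_id), .groups = "drop")
  )
}

#' Bin-by-sample breakpoint presence matrix
#'
#' 0/1 matrix (as a tibble) with one row per bin and one column per sample;
#' an entry is 1 iff the sample has at least one breakpoint in the bin. This
#' is the data behind recurrence heat maps; rendering is left to the caller.
#'
#' @param events Breakpoint tibble.
#' @param bins Bin tibble (rows of the output, in this order).
#' @param samples Sample ids (columns); default: samples present in `events`.
#' @return Tibble `bin_id`, `chrom`, `start_bp`, then one 0/1 column per
#'   sample.
#' @export
presence_matrix <- function(events, bins, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(events$sample_id))
  out <- select(bins, "bin_id", "chrom", "start_bp")
  for (s in samples) {
    hit <- unique(events$bin_id[events$sample_id == s])
    out[[s]] <- as.integer(out$bin_id %in% hit)
  }
  out
}
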