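#' Segmentation parameters
#'
#' Parameters of circular binary segmentation (CBS) with permutation
#' significance and SD-based undo pruning. The defaults are the standard
#' stringent setting for SNP-array copy-number work: split significance
#' `alpha = 0.001`, at least 4 SNPs per segment, and post-hoc merging of
#' adjacent segments whose means differ by less than 0.5 noise SDs.
#'
#' @param alpha Permutation significance level for accepting a split,
#'   in (0, 1).
#' @param min_width Minimum number of SNPs in any emitted segment (>= 2).
#' @param undo_sd Undo multiplier: adjacent segments closer than
#'   `undo_sd * noise SD` in mean are merged (>= 0; 0 disables undo).
#' @param n_permutations Permutations per split test (>= 100). Note the
#'   smallest attainable p-value is `1 / (n_permutations + 1)`, which must
#'   not exceed `alpha` for any split to be accepted.
#' @param seed Integer seed for the permutation RNG.
#' @return A `seg_params` list.
#' @export
seg_params <- function(alpha = 0.001, min_width = 4, undo_sd = 0.5,
                       n_permutations = 10000, seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  if (min_width < 2) abort("min_width must be >= 2")
  if (undo_sd < 0) abort("undo_sd must be >= 0")
  if (n_permutations < 100) abort("n_permutations must be >= 100")
  if (1 / (n_permutations + 1) > alpha) {
    warn("n_permutations too small for alpha: no split can ever be accepted")
  }
  structure(
    list(alpha = alpha, min_width = as.integer(min_width), undo_sd = undo_sd,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed)),
    class = "seg_params"
  )
}

#' Robust per-chromosome noise SD
#'
#' Estimates the SD of the additive log2-scale noise from the median absolute
#' first difference, `median(|x[t+1] - x[t]|) / 0.9539` (the scaled MAD of
#' consecutive differences). True copy-number shifts affect only a handful of
#' differences and so leave the median essentially untouched, unlike the raw
#' SD, which is inflated by segment structure.
#'
#' @param x Numeric vector of log2 ratios (length >= 2), NA allowed (dropped).
#' @return Non-negative noise SD estimate.
#' @export
#' @examples
#' estimate_noise_sd(rnorm(1000, sd = 0.2))
estimate_noise_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("need at least 2 values to estimate noise SD")
  median(abs(diff(x))) / 0.9539
}

# String-stable substream so a sample's segmentation does not depend on which
# other samples are in the call.
string_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

# Recursive CBS on one chromosome's unmasked values; returns the sorted
# 1-based end indices of the segments (the last is always length(x)).
cbs_one_chrom <- function(x, params) {
  n <- length(x)
  w <- params$min_width
  stop_count <- ceiling(params$alpha * (1 + params$n_permutations))
  ends <- n
  stack <- list(c(1L, n))
  while (length(stack)) {
    lohi <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- lohi[1]; hi <- lohi[2]
    m <- hi - lo + 1L
    if (m < 2L * w) next
    seg <- x[lo:hi]
    arc <- cbs_best_arc_cpp(seg, w)
    if (arc$i < 0 || arc$t <= 0) next
    pt <- cbs_perm_test_cpp(seg, arc$t, w, params$n_permutations, stop_count)
    if (pt$exceed >= stop_count) next                       # p > alpha
    p <- (1 + pt$exceed) / (1 + params$n_permutations)
    if (p > params$alpha) next
    i <- arc$i; j <- arc$j
    if (i > 0) {
      ends <- c(ends, lo + i - 1L)
      stack[[length(stack) + 1]] <- c(lo, lo + i - 1L)
    }
    if (j < m) {
      ends <- c(ends, lo + j - 1L)
      stack[[length(stack) + 1]] <- c(lo + j, hi)
    }
    stack[[length(stack) + 1]] <- c(lo + i, lo + j - 1L)
  }
  sort(unique(ends))
}

# Merge adjacent segments whose means are closer than undo_sd * noise_sd,
# always collapsing the currently closest pair first.
sd_undo <- function(ends, x, undo_sd, noise_sd) {
  thr <- undo_sd * noise_sd
  starts <- c(1L, head(ends, -1) + 1L)
  sums <- purrr::map2_dbl(starts, ends, ~sum(x[.x:.y]))
  ns <- ends - starts + 1
  while (length(ends) > 1) {
    means <- sums / ns
    d <- abs(diff(means))
    k <- which.min(d)
    if (d[k] >= thr) break
    sums[k] <- sums[k] + sums[k + 1]
    ns[k] <- ns[k] + ns[k + 1]
    ends[k] <- ends[k + 1]
    sums <- sums[-(k + 1)]; ns <- ns[-(k + 1)]; ends <- ends[-(k + 1)]
  }
  ends
}

#' Segment log2-ratio tracks by circular binary segmentation
#'
#' Partitions each sample's per-chromosome log2-ratio sequence into segments
#' of constant copy number. At every recursion step the arc of the circularly
#' joined sequence maximizing the absolute pooled two-sample t statistic
#' against its complement is found (subject to `min_width` on every resulting
#' piece) and the split is accepted when its permutation p-value
#' `(1 + exceedances) / (1 + n_permutations)` is at most `alpha`; accepted
#' pieces are segmented recursively. Afterwards, adjacent segments whose
#' means differ by less than `undo_sd` times the chromosome's robust noise SD
#' (see [estimate_noise_sd()]) are merged, closest pair first. Masked (`NA`)
#' SNPs are skipped; a chromosome with fewer than `min_width` usable SNPs
#' yields a single segment.
#'
#' @param ratios log2-ratio matrix tibble from [log2_ratio()] (or read back
#'   from disk), columns `snp_id`, `chrom`, `position` plus sample columns.
#' @param params A [seg_params()].
#' @param samples Sample columns to segment (default: all).
#' @return A `cbs_segmentation` tibble with columns `sample_id`, `chrom`,
#'   `start_bp`, `end_bp` (positions of the first and last member SNP),
#'   `n_snps`, `mean_log2`; attributes `params` and `noise_sd` (per
#'   sample x chromosome estimates used for the undo step).
#' @export
cbs_segment <- function(ratios, params = seg_params(), samples = NULL) {
  stopifnot(inherits(params, "seg_params"))
  samples <- sample_cols_of(ratios, samples)
  if (length(samples) == 0) abort("no sample columns to segment")
  chroms <- unique(ratios$chrom)
  seg_rows <- list()
  sd_rows <- list()
  for (s in samples) {
    set.seed(string_seed(params$seed, s))
    for (chr in chroms) {
      sel <- ratios$chrom == chr & !is.na(ratios[[s]])
      x <- ratios[[s]][sel]
      pos <- ratios$position[sel]
      n <- length(x)
      if (n == 0) next
      nsd <- if (n >= 2) estimate_noise_sd(x) else 0
      ends <- if (n < 2 * params$min_width) n else cbs_one_chrom(x, params)
      if (length(ends) > 1 && params$undo_sd > 0) {
        ends <- sd_undo(ends, x, params$undo_sd, nsd)
      }
      starts <- c(1L, head(ends, -1) + 1L)
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        sample_id = s, chrom = chr,
        start_bp = pos[starts], end_bp = pos[ends],
        n_snps = as.integer(ends - starts + 1),
        mean_log2 = purrr::map2_dbl(starts, ends, ~mean(x[.x:.y]))
      )
      sd_rows[[length(sd_rows) + 1]] <- tibble(
        sample_id = s, chrom = chr, noise_sd = nsd, n_snps_used = n
      )
    }
  }
  if (!length(seg_rows)) abort("empty track: nothing to segment")
  out <- bind_rows(seg_rows)
  attr(out, "params") <- params
  attr(out, "noise_sd") <- bind_rows(sd_rows)
  class(out) <- c("cbs_segmentation", class(out))
  out
}

#' @export
tidy.cbs_segmentation <- function(x, ...) {
  out <- x
  attr(out, "params") <- NULL
  attr(out, "noise_sd") <- NULL
  class(out) <- setdiff(class(out), "cbs_segmentation")
  as_tibble(out)
}

#' @export
glance.cbs_segmentation <- function(x, ...) {
  tidy(x) %>%
    group_by(.data$sample_id) %>%
    summarise(n_chroms = n_distinct(.data$chrom), n_segments = n()) %>%
    summarise(
      n_samples = n(),
      mean_segments_per_sample = mean(.data$n_segments),
      n_segments = sum(.data$n_segments),
      n_chroms = max(.data$n_chroms)
    )
}

#' Read / write SEG-style segment tables
#'
#' Tab-separated with header `sample_id`, `chrom`, `start_bp`, `end_bp`,
#' `n_snps`, `mean_log2` — one row per constant-copy-number segment,
#' compatible with common SEG consumers.
#'
#' @param path File path.
#' @return Segment tibble.
#' @export
read_seg <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "chrom", "start_bp", "end_bp", "n_snps", "mean_log2")
  if (!all(need %in% names(x))) {
    abort(paste0("SEG file must have columns: ", paste(need, collapse = ", ")))
  }
  mutate(x, chrom = as.character(.data$chrom))
}

#' @param segments Segment tibble to write.
#' @rdname read_seg
#' @export
write_seg <- function(segments, path) {
  readr::write_tsv(
    select(as_tibble(segments), "sample_id", "chrom", "start_bp", "end_bp",
           "n_snps", "mean_log2"),
    path
  )
  invisible(path)
}
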