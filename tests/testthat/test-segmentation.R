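# independent naive oracle: best circular arc by pooled two-sample t,
# computed with plain var()/mean() loops
oracle_best_arc <- function(x, w) {
  n <- length(x)
  best <- c(t = -1, i = NA, j = NA)
  for (i in c(0, w:(n - w))) {
    for (j in (i + w):n) {
      if (i == 0 && j == n) next
      suf <- n - j
      if (suf != 0 && suf < w) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
      se <- sqrt(ss / (n - 2) * (1 / length(arc) + 1 / length(comp)))
      t <- if (se > 0) abs(mean(arc) - mean(comp)) / se else Inf
      if (t > best["t"]) best <- c(t = t, i = i, j = j)
    }
  }
  best
}

ratios_from_values <- function(x, chrom = "chrA", spacing = 1000) {
  tibble(
    snp_id = sprintf("s%04d", seq_along(x)), chrom = chrom,
    position = seq_along(x) * spacing, s1 = x
  )
}

test_that("noise SD estimator is calibrated and shift-insensitive", {
  withr::with_seed(1, x <- rnorm(10000, sd = 0.37))
  expect_lt(abs(estimate_noise_sd(x) - 0.37) / 0.37, 0.05)

  steps <- rep(c(0, 1, -2, 5), each = 50)
  expect_equal(estimate_noise_sd(steps), 0)

  sq <- rep(c(0.3, -0.3), 100)  # worst case: every difference is a shift
  expect_lt(estimate_noise_sd(sq), 3 * 0.3)
  expect_error(estimate_noise_sd(1), "at least 2")
})

test_that("constant tracks yield a single segment with the exact mean", {
  r <- ratios_from_values(rep(0.25, 50))
  seg <- cbs_segment(r, seg_params(n_permutations = 100, alpha = 0.5))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean_log2, 0.25)
  expect_equal(seg$n_snps, 50L)
})

test_that("a single step is split exactly where the t oracle says", {
  withr::with_seed(7, x <- c(rnorm(30, 0, 0.05), rnorm(30, 1, 0.05)))
  seg <- cbs_segment(ratios_from_values(x),
                     seg_params(n_permutations = 1000, seed = 1))
  expect_equal(nrow(seg), 2)
  o <- oracle_best_arc(x, 4)
  # the oracle's best arc cuts the sequence at the true changepoint (the
  # prefix arc (0, 30] and the suffix arc (30, 60] are tied and equivalent)
  cuts <- setdiff(unname(o[c("i", "j")]), c(0, 60))
  expect_equal(cuts, 30)
  expect_equal(seg$n_snps, c(30L, 30L))
  expect_equal(seg$mean_log2, c(mean(x[1:30]), mean(x[31:60])))
})

test_that("three planted segments are recovered near the true changepoints", {
  hits <- 0
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      x <- c(rnorm(40, 0, 0.1), rnorm(40, 0.8, 0.1), rnorm(40, 0, 0.1))
    })
    seg <- cbs_segment(ratios_from_values(x),
                       seg_params(n_permutations = 1000, seed = s))
    if (nrow(seg) == 3) {
      ends <- cumsum(seg$n_snps)
      if (all(abs(ends[1:2] - c(40, 80)) <= 2)) hits <- hits + 1
    }
  }
  expect_gte(hits, 4)
})

test_that("sd-undo merges segments closer than undo_sd * noise SD", {
  withr::with_seed(11, x <- c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05)))
  r <- ratios_from_values(x)
  split <- cbs_segment(r, seg_params(undo_sd = 0.5, n_permutations = 1000))
  expect_equal(nrow(split), 2)
  # a huge undo multiplier folds even a strong step back together
  merged <- cbs_segment(r, seg_params(undo_sd = 50, n_permutations = 1000))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$mean_log2, mean(x))

  # post-undo separation: adjacent means differ by >= undo_sd * noise SD
  nsd <- attr(split, "noise_sd")$noise_sd[1]
  expect_gte(abs(diff(split$mean_log2)), 0.5 * nsd)
})

test_that("segments tile each chromosome and means are recomputable", {
  coh <- small_cohort(noise_sd = 0.1, n_tumor = 2, seed = 4)
  r <- cohort_ratios(coh)
  seg <- cbs_segment(r, seg_params(n_permutations = 1000, seed = 2))
  for (s in unique(seg$sample_id)) {
    for (chr in unique(seg$chrom)) {
      sub <- seg[seg$sample_id == s & seg$chrom == chr, ]
      vals <- r[[s]][r$chrom == chr & !is.na(r[[s]])]
      pos <- r$position[r$chrom == chr & !is.na(r[[s]])]
      expect_equal(sum(sub$n_snps), length(vals))
      expect_true(all(diff(sub$start_bp) > 0))
      expect_equal(sub$start_bp[1], pos[1])
      expect_equal(sub$end_bp[nrow(sub)], pos[length(pos)])
      # mean consistency, recomputed from the member SNPs
      ends <- cumsum(sub$n_snps)
      starts <- c(1, head(ends, -1) + 1)
      expect_equal(sub$mean_log2,
                   mapply(function(a, b) mean(vals[a:b]), starts, ends),
                   tolerance = 1e-9)
    }
  }
})

test_that("segmentation is deterministic given the seed", {
  coh <- small_cohort(noise_sd = 0.15, n_tumor = 2, seed = 8)
  r <- cohort_ratios(coh)
  p <- seg_params(n_permutations = 500, alpha = 0.01, seed = 33)
  expect_identical(tidy(cbs_segment(r, p)), tidy(cbs_segment(r, p)))
})

test_that("seg params are validated", {
  expect_error(seg_params(alpha = 0), "alpha")
  expect_error(seg_params(min_width = 1), "min_width")
  expect_error(seg_params(n_permutations = 10), "n_permutations")
  expect_warning(seg_params(alpha = 0.001, n_permutations = 200),
                 "too small")
})

test_that("SEG round trip preserves the segment table", {
  coh <- small_cohort(noise_sd = 0, n_tumor = 1)
  seg <- cbs_segment(cohort_ratios(coh), seg_params(n_permutations = 100,
                                                    alpha = 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_seg(seg, path)
  back <- read_seg(path)
  expect_equal(as.data.frame(back), as.data.frame(tidy(seg)))
})
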