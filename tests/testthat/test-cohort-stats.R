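mini_manifest <- function() {
  tibble(
    sample_id = c("n1", "n2", "t1", "t2", "t3"),
    group = c("nmce", "nmce", "tum", "tum", "tum"),
    role = c("reference", "control", "tumor", "tumor", "tumor")
  )
}

test_that("count_by_bin deduplicates samples but keeps event totals", {
  bins <- make_bins(c(chrA = 3e5))
  ev <- tibble(sample_id = c("t1", "t1"), chrom = "chrA",
               boundary_bp = c(10, 20), bin_id = "chrA:1",
               delta = 1, n_left = 10L, n_right = 10L)
  cnt <- count_by_bin(ev, mini_manifest(), bins)
  row <- cnt[cnt$bin_id == "chrA:1" & cnt$group == "tum", ]
  expect_equal(row$sample_count, 1L)
  expect_equal(row$event_count, 2L)
  expect_equal(attr(cnt, "group_sizes"), c(nmce = 2L, tum = 3L))

  empty <- count_by_bin(ev[0, ], mini_manifest(), bins)
  expect_true(all(empty$sample_count == 0) && all(empty$event_count == 0))
  expect_equal(nrow(empty), nrow(bins) * 2)

  bad <- dplyr::mutate(ev, sample_id = "ghost")
  expect_error(count_by_bin(bad, mini_manifest(), bins), "ghost")
})

test_that("random event fixtures match a hash-and-count oracle", {
  bins <- make_bins(c(chrA = 1e6), bin_size = 1e5)
  man <- mini_manifest()
  withr::with_seed(13, {
    ev <- tibble(
      sample_id = sample(man$sample_id, 300, replace = TRUE),
      chrom = "chrA",
      boundary_bp = sample(1e6, 300)
    )
  })
  ev$bin_id <- paste0("chrA:", (ev$boundary_bp - 1) %/% 1e5 * 1e5 + 1)
  cnt <- count_by_bin(ev, man, bins)
  key <- paste(ev$bin_id, man$group[match(ev$sample_id, man$sample_id)])
  for (r in seq_len(nrow(cnt))) {
    k <- paste(cnt$bin_id[r], cnt$group[r])
    expect_equal(cnt$event_count[r], sum(key == k))
    expect_equal(
      cnt$sample_count[r],
      length(unique(ev$sample_id[key == k]))
    )
  }
  # totals per group are preserved
  tot <- cnt %>% dplyr::group_by(group) %>%
    dplyr::summarise(n = sum(event_count))
  expect_equal(sum(tot$n), nrow(ev))
})

test_that("odds ratios reproduce all printed two-decimal values", {
  # the ten distinct (a, c) pairs printed for T = 111 tumors, N = 20 NMCE
  cases <- tibble(
    a = c(48, 32, 23, 40, 26, 25, 24, 36, 9, 22),
    c = c(1, 0, 0, 3, 0, 0, 0, 3, 0, 0),
    printed = c(14.48, 16.46, 10.68, 3.19, 12.47, 11.86, 11.26, 2.72,
                3.73, 10.11)
  )
  got <- odds_ratio(cases$a, cases$c, 111, 20)
  expect_equal(round(got$odds_ratio, 2), cases$printed, tolerance = 0.005)
  expect_equal(got$corrected, cases$c == 0)

  expect_equal(odds_ratio(10, 10, 20, 20)$odds_ratio, 1.0)
  expect_error(odds_ratio(20, 1, 20, 20), "saturated")
  expect_error(odds_ratio(-1, 0, 20, 20), "counts")
})

test_that("odds ratios are reciprocal and monotone where uncorrected", {
  for (a in c(5, 17, 40)) {
    for (c in c(2, 9)) {
      lhs <- odds_ratio(a, c, 111, 20)$odds_ratio
      rhs <- odds_ratio(c, a, 20, 111)$odds_ratio
      expect_equal(lhs * rhs, 1, tolerance = 1e-12)
    }
  }
  ors_a <- odds_ratio(1:19, 5, 20, 20)$odds_ratio
  expect_true(all(diff(ors_a) > 0))
  ors_c <- odds_ratio(10, 1:19, 20, 20)$odds_ratio
  expect_true(all(diff(ors_c) < 0))
})

test_that("top_regions applies the ceiling threshold and genome ordering", {
  bins <- make_bins(c(chrA = 1e6), bin_size = 1e5)
  man <- tibble(sample_id = sprintf("t%03d", 1:111), group = "tum",
                role = "tumor")
  # bins 1..10 carried by 30, 23, 22, 23, 0, ... samples
  counts_wanted <- c(30, 23, 22, 23, rep(0, 6))
  ev <- purrr::imap(counts_wanted, function(k, i) {
    if (k == 0) return(NULL)
    tibble(sample_id = man$sample_id[seq_len(k)], chrom = "chrA",
           boundary_bp = (i - 1) * 1e5 + 1, bin_id = bins$bin_id[i])
  }) %>% dplyr::bind_rows()
  cnt <- count_by_bin(ev, man, bins)
  top <- top_regions(cnt, "tum", 0.20)
  # 22/111 < 20% is excluded: the minimum qualifying count is 23
  expect_equal(top$sample_count, c(30, 23, 23))
  expect_equal(top$bin_id, c("chrA:1", "chrA:100001", "chrA:300001"))
  expect_equal(min(top$sample_count), 23)
  # smallest k with k/917 >= 0.2
  expect_equal(min(which((1:917) / 917 >= 0.2)), 184)
  expect_error(top_regions(cnt, "tum", 0), "fraction")
  expect_error(top_regions(cnt, "nope"), "unknown group")
})

test_that("recurrence_fraction counts bins with any event", {
  bins <- make_bins(c(chrA = 1e6), bin_size = 1e5)
  man <- mini_manifest()
  ev <- tibble(sample_id = "t1", chrom = "chrA", boundary_bp = c(5, 2e5 + 5),
               bin_id = c("chrA:1", "chrA:200001"))
  rf <- recurrence_fraction(count_by_bin(ev, man, bins))
  expect_equal(rf$n_bins, 10)
  expect_equal(rf$n_hit, 2)
  expect_equal(rf$percent, 20)

  zero <- recurrence_fraction(count_by_bin(ev[0, ], man, bins))
  expect_equal(zero$fraction, 0)
  full <- tibble(sample_id = "t1", chrom = "chrA",
                 boundary_bp = bins$start_bp, bin_id = bins$bin_id)
  expect_equal(recurrence_fraction(count_by_bin(full, man, bins))$percent, 100)
})

test_that("region_summary reports events, samples, and sub-profiles", {
  man <- tibble(sample_id = sprintf("s%02d", 1:20), group = "tum",
                role = "tumor")
  # 64 events from 13 samples inside the query interval, echoing a
  # fragile-site style report
  withr::with_seed(3, {
    inside <- tibble(
      sample_id = sample(man$sample_id[1:13], 64, replace = TRUE),
      chrom = "chr16", boundary_bp = sample(78e6:79e6, 64),
      bin_id = "x"
    )
    while (length(unique(inside$sample_id)) < 13) {
      inside$sample_id <- sample(man$sample_id[1:13], 64, replace = TRUE)
    }
  })
  outside <- tibble(sample_id = "s20", chrom = "chr16",
                    boundary_bp = 10, bin_id = "y")
  rs <- region_summary(dplyr::bind_rows(inside, outside), man,
                       "chr16", 78e6, 79e6)
  expect_equal(rs$summary$event_count, 64)
  expect_equal(rs$summary$sample_count, 13)
  expect_equal(sum(rs$by_group$event_count), 64)
  expect_equal(sum(rs$by_bin$event_count), 64)

  none <- region_summary(inside, man, "chr16", 1, 100)
  expect_equal(none$summary$event_count, 0)
  expect_equal(none$summary$sample_count, 0)
  expect_error(region_summary(inside, man, "chr16", 100, 1), "inverted")
})

test_that("presence matrix is 0/1 and consistent with sample counts", {
  bins <- make_bins(c(chrA = 5e5), bin_size = 1e5)
  man <- mini_manifest()
  ev <- tibble(sample_id = c("t1", "t1", "t2"), chrom = "chrA",
               boundary_bp = c(5, 15, 2e5 + 5),
               bin_id = c("chrA:1", "chrA:1", "chrA:200001"))
  pm <- presence_matrix(ev, bins, man$sample_id)
  m <- as.matrix(pm[man$sample_id])
  expect_true(all(m %in% 0:1))
  expect_equal(unname(m[1, "t1"]), 1)
  expect_equal(unname(m[3, "t2"]), 1)
  # row sums equal per-bin distinct-sample counts pooled over groups
  cnt <- count_by_bin(ev, man, bins)
  per_bin <- cnt %>% dplyr::group_by(bin_id) %>%
    dplyr::summarise(n = sum(sample_count))
  expect_equal(rowSums(m), per_bin$n[match(pm$bin_id, per_bin$bin_id)],
               ignore_attr = TRUE)
})
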