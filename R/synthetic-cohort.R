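#' Describe a planted copy-number region
#'
#' A planted region is a genomic interval whose member SNPs are shifted by
#' `delta_log2` (on the log2 scale) in every sample that "expresses" the
#' region. Expression is drawn per sample with a group-specific penetrance,
#' so the region's two boundaries become recurrent breakpoints with a known
#' per-group recurrence rate — the ground truth every downstream stage is
#' checked against.
#'
#' @param chrom Chromosome name.
#' @param start_bp,end_bp 1-based inclusive interval bounds, `start_bp < end_bp`.
#' @param delta_log2 Signed log2 copy-number shift of the altered segment
#'   (1.0 = one doubling).
#' @param penetrance Named numeric vector: probability, per group name, that
#'   a sample of that group expresses the region. Groups not named get 0.
#'
#' @return One-row tibble with a list-column `penetrance`.
#' @export
#' @examples
#' planted_region("chrA", 3e6 + 1, 4.5e6, delta_log2 = 1,
#'                penetrance = c(tumor = 0.45))
planted_region <- function(chrom, start_bp, end_bp, delta_log2, penetrance) {
  if (start_bp >= end_bp) abort("start_bp must be < end_bp")
  if (any(penetrance < 0 | penetrance > 1)) {
    abort("penetrances must lie in [0, 1]")
  }
  if (is.null(names(penetrance)) || any(!nzchar(names(penetrance)))) {
    abort("`penetrance` must be named by group")
  }
  tibble(
    chrom = as.character(chrom),
    start_bp = as.numeric(start_bp),
    end_bp = as.numeric(end_bp),
    delta_log2 = as.numeric(delta_log2),
    penetrance = list(penetrance)
  )
}

#' Configure a synthetic SNP-array cohort
#'
#' The default design mirrors a realistic multi-cohort study: a panel of 15
#' reference samples (blood-derived, used to build the averaged reference
#' track), 5 additional non-malignant controls, and 111 tumor samples, with
#' multiplicative log-normal intensity noise of 0.2 on the log2 scale.
#'
#' @param n_reference Number of reference-panel samples (>= 1). Reference
#'   samples never express planted regions.
#' @param groups Data frame with columns `group`, `role`
#'   (one of `"reference"`, `"control"`, `"tumor"`, `"cell_line"`) and
#'   `n_samples`. The reference panel is added automatically; do not list it.
#' @param planted_regions Tibble of [planted_region()] rows (may be empty).
#' @param noise_sd Standard deviation of per-SNP Gaussian noise on the log2
#'   scale (>= 0); intensities get the multiplicative factor `2^noise`.
#' @param baseline_intensity Positive baseline A+B intensity (arbitrary
#'   array units).
#' @param seed Master integer seed; per-sample substreams are derived from it
#'   so that adding samples does not reshuffle existing ones.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_reference = 15,
                          groups = tibble(
                            group = c("control", "tumor"),
                            role = c("control", "tumor"),
                            n_samples = c(5, 111)
                          ),
                          planted_regions = NULL,
                          noise_sd = 0.2,
                          baseline_intensity = 2000,
                          seed = 1L) {
  groups <- as_tibble(groups)
  if (!all(c("group", "role", "n_samples") %in% names(groups))) {
    abort("`groups` needs columns group, role, n_samples")
  }
  if (n_reference < 1) abort("n_reference must be >= 1")
  if (nrow(groups) == 0) abort("at least one non-reference group is required")
  if (any(groups$n_samples < 1)) abort("all group sizes must be >= 1")
  bad_role <- setdiff(groups$role, c("reference", "control", "tumor", "cell_line"))
  if (length(bad_role)) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (baseline_intensity <= 0) abort("baseline_intensity must be positive")
  if (is.null(planted_regions)) {
    planted_regions <- tibble(
      chrom = character(), start_bp = numeric(), end_bp = numeric(),
      delta_log2 = numeric(), penetrance = list()
    )
  }
  planted_regions <- as_tibble(planted_regions)
  check_region_overlap(planted_regions)
  structure(
    list(
      n_reference = as.integer(n_reference),
      groups = groups,
      planted_regions = planted_regions,
      noise_sd = noise_sd,
      baseline_intensity = baseline_intensity,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Overlapping planted regions would make boundary truth ambiguous; reject.
check_region_overlap <- function(regions) {
  if (nrow(regions) < 2) return(invisible(regions))
  by_chr <- split(regions, regions$chrom)
  for (r in by_chr) {
    r <- arrange(r, .data$start_bp)
    if (nrow(r) > 1 && any(r$start_bp[-1] <= r$end_bp[-nrow(r)])) {
      abort("planted regions must not overlap within a chromosome")
    }
  }
  invisible(regions)
}

#' Simulate an intensity cohort with planted breakpoint regions
#'
#' Generates, for every sample, a per-SNP total (A+B) intensity vector
#' `baseline * 2^(delta + noise)`, where `delta` is the summed log2 shift of
#' the planted regions the sample expresses and `noise ~ N(0, noise_sd)`
#' independently per SNP. Whether a sample expresses a region is a Bernoulli
#' draw with the region's penetrance for the sample's group; reference-panel
#' samples never express regions. Fully deterministic given the config seed.
#'
#' @param map A [snp_map].
#' @param config A [cohort_config()].
#'
#' @return A `cnv_cohort` list with elements
#'   `intensities` (tibble: `snp_id`, `chrom`, `position`, one column per
#'   sample), `manifest` (tibble: `sample_id`, `group`, `role`), `truth`
#'   (tibble: `sample_id`, `group`, `chrom`, `boundary_bp`, `side`,
#'   `delta_log2` — two rows per expressed region, at the region's start and
#'   end), and the `map` and `config` used.
#' @export
synthesize_cohort <- function(map, config) {
  stopifnot(inherits(map, "snp_map"), inherits(config, "cohort_config"))
  regions <- config$planted_regions
  if (nrow(regions)) {
    known <- map$chrom_lengths
    reg_chk <- left_join(regions, known, by = "chrom")
    if (any(is.na(reg_chk$length)) || any(reg_chk$end_bp > reg_chk$length)) {
      abort("planted regions must lie within the map's chromosomes")
    }
  }

  manifest <- bind_rows(
    tibble(
      sample_id = sprintf("reference_%03d", seq_len(config$n_reference)),
      group = "reference", role = "reference"
    ),
    purrr::pmap(config$groups, function(group, role, n_samples) {
      tibble(
        sample_id = sprintf("%s_%03d", group, seq_len(n_samples)),
        group = group, role = role
      )
    }) %>% bind_rows()
  )
  if (anyDuplicated(manifest$sample_id)) abort("group names collide")

  snps <- map$snps
  n_snp <- nrow(snps)
  # per-region SNP membership mask (regions are non-overlapping)
  region_mask <- purrr::map(seq_len(nrow(regions)), function(i) {
    snps$chrom == regions$chrom[i] &
      snps$position >= regions$start_bp[i] &
      snps$position <= regions$end_bp[i]
  })

  truth_rows <- list()
  sample_cols <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    grp <- manifest$group[i]
    is_ref <- identical(manifest$role[i], "reference")
    sub <- substream_seed(config$seed, i)
    # draw (region expression, per-SNP noise) in the sample's own substream
    draws <- with_seed(sub, {
      pen <- purrr::map_dbl(regions$penetrance, function(p) {
        if (!is_ref && grp %in% names(p)) p[[grp]] else 0
      })
      list(
        expressed = runif(length(pen)) < pen,
        eps = rnorm(n_snp, 0, config$noise_sd)
      )
    })
    delta <- numeric(n_snp)
    for (r in which(draws$expressed)) {
      delta[region_mask[[r]]] <- delta[region_mask[[r]]] + regions$delta_log2[r]
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        sample_id = sid, group = grp,
        chrom = regions$chrom[r],
        boundary_bp = c(regions$start_bp[r], regions$end_bp[r]),
        side = c("start", "end"),
        delta_log2 = regions$delta_log2[r]
      )
    }
    sample_cols[[i]] <- config$baseline_intensity * 2^(delta + draws$eps)
  }
  intensities <- bind_cols(
    snps,
    as_tibble(setNames(sample_cols, manifest$sample_id))
  )
  truth <- if (length(truth_rows)) bind_rows(truth_rows) else tibble(
    sample_id = character(), group = character(), chrom = character(),
    boundary_bp = numeric(), side = character(), delta_log2 = numeric()
  )
  structure(
    list(intensities = intensities, manifest = manifest, truth = truth,
         map = map, config = config),
    class = "cnv_cohort"
  )
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("<cnv_cohort> ", nrow(x$manifest), " samples x ",
      nrow(x$intensities), " SNPs; ",
      nrow(x$truth), " planted boundary record(s)\n", sep = "")
  invisible(x)
}

#' Expected boundary bins of the planted truth
#'
#' Translates planted boundary coordinates into the 100 kb bins a correct
#' segmentation would report. A breakpoint is anchored at the first SNP of
#' the downstream segment: for a region start that is the first SNP at or
#' after the start; for a region end, the first SNP after the end (where the
#' background resumes). Boundaries with no downstream SNP on the chromosome
#' are returned with `NA` bin.
#'
#' @param truth Truth tibble from [synthesize_cohort()].
#' @param map The cohort's [snp_map].
#' @param bins Bin tibble from [make_bins()].
#' @return `truth` with added `boundary_snp_bp` and `bin_id`.
#' @export
truth_bins <- function(truth, map, bins) {
  snps <- map$snps
  find_snp <- function(chrom, bp, side) {
    pos <- snps$position[snps$chrom == chrom]
    cand <- if (side == "start") pos[pos >= bp] else pos[pos > bp]
    if (length(cand)) cand[1] else NA_real_
  }
  truth <- truth %>%
    mutate(boundary_snp_bp = purrr::pmap_dbl(
      list(.data$chrom, .data$boundary_bp, .data$side), find_snp
    ))
  truth$bin_id <- assign_bin(truth$chrom, truth$boundary_snp_bp, bins)
  truth
}

#' Write a synthetic cohort to disk
#'
#' Writes the intensity matrix (`intensities.tsv`: `snp_id`, `chrom`,
#' `position`, one column per sample), the sample manifest
#' (`manifest.tsv`: `sample_id`, `group`, `role`), the planted-boundary truth
#' (`truth.tsv`: `sample_id`, `chrom`, `boundary_bp`) and the chromosome
#' lengths (`chrom_lengths.tsv`), all tab-separated.
#'
#' @param cohort A `cnv_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    truth = file.path(dir, "truth.tsv"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv")
  )
  readr::write_tsv(cohort$intensities, paths[["intensities"]])
  readr::write_tsv(cohort$manifest, paths[["manifest"]])
  readr::write_tsv(
    select(cohort$truth, "sample_id", "chrom", "boundary_bp"),
    paths[["truth"]]
  )
  readr::write_tsv(cohort$map$chrom_lengths, paths[["chrom_lengths"]])
  invisible(paths)
}
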