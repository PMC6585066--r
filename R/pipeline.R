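#' Configure an end-to-end pipeline run
#'
#' Bundles the file paths and stage parameters of a full analysis: intensity
#' matrix -> reference averaging -> log2 ratios -> CBS segmentation ->
#' breakpoint calling -> per-bin cohort statistics -> fragile-site overlap.
#'
#' @param intensities Path to the SNP-keyed intensity matrix TSV.
#' @param manifest Path to the sample manifest TSV.
#' @param chrom_lengths Path to a `chrom`/`length` TSV.
#' @param out_dir Output directory.
#' @param fragile_sites Optional path to a fragile-site table.
#' @param fragile_format `"tsv"` or `"bed"` (see [read_fragile_sites()]).
#' @param seg A [seg_params()].
#' @param rule A [breakpoint_rule()].
#' @param bin_size Bin width in bp (default 100 kb).
#' @param excluded_chroms Chromosomes dropped before binning.
#' @param top_fraction Recurrence threshold for [top_regions()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(intensities, manifest, chrom_lengths, out_dir,
                            fragile_sites = NULL, fragile_format = "tsv",
                            seg = seg_params(), rule = breakpoint_rule(),
                            bin_size = 100000,
                            excluded_chroms = c("chrY", "Y", "chrM", "MT"),
                            top_fraction = 0.20) {
  stopifnot(inherits(seg, "seg_params"), inherits(rule, "breakpoint_rule"))
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    abort("top_fraction must be in (0, 1]")
  }
  structure(
    list(intensities = intensities, manifest = manifest,
         chrom_lengths = chrom_lengths, fragile_sites = fragile_sites,
         fragile_format = fragile_format, out_dir = out_dir, seg = seg,
         rule = rule, bin_size = bin_size,
         excluded_chroms = excluded_chroms, top_fraction = top_fraction),
    class = "pipeline_config"
  )
}

#' Validate pipeline inputs
#'
#' Checks, without running any stage, that the referenced files exist, the
#' SNP map inside the intensity matrix is sorted, every matrix sample column
#' is in the manifest (and vice versa), and chromosome names are consistent
#' with the length table.
#'
#' @param config A [pipeline_config()].
#' @return Tibble `severity` (`"fatal"`/`"warning"`), `message`; zero rows
#'   when everything is consistent.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(severity, msg) {
    issues[[length(issues) + 1]] <<- tibble(severity = severity, message = msg)
  }
  paths <- c(intensities = config$intensities, manifest = config$manifest,
             chrom_lengths = config$chrom_lengths)
  if (!is.null(config$fragile_sites)) {
    paths <- c(paths, fragile_sites = config$fragile_sites)
  }
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      note("fatal", paste0("missing input file (", nm, "): ", paths[[nm]]))
    }
  }
  if (length(issues)) return(bind_rows(issues))

  mat <- read_intensity_matrix(config$intensities)
  man <- read_manifest(config$manifest)
  lens <- as_chrom_lengths(
    readr::read_tsv(config$chrom_lengths, show_col_types = FALSE,
                    progress = FALSE)
  )
  sorted <- mat %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$position, strictly = TRUE))
  for (chr in sorted$chrom[!sorted$ok]) {
    note("fatal", paste0("SNP map unsorted on chromosome ", chr))
  }
  cols <- sample_cols_of(mat)
  for (s in setdiff(cols, man$sample_id)) {
    note("fatal", paste0("sample column missing from manifest: ", s))
  }
  for (s in setdiff(man$sample_id, cols)) {
    note("fatal", paste0("manifest sample absent from matrix: ", s))
  }
  for (chr in setdiff(unique(mat$chrom), lens$chrom)) {
    note("warning",
         paste0("chromosome in data but not in length table: ", chr))
  }
  if (length(issues)) bind_rows(issues) else {
    tibble(severity = character(), message = character())
  }
}

#' Run the full breakpoint-recurrence pipeline
#'
#' Executes every stage on the configured inputs and writes the result bundle
#' to `out_dir`: `log2_ratios.tsv`, `segments.seg.tsv`, `events.tsv`,
#' `bin_counts.tsv`, `or_table.tsv`, `top_regions.tsv`,
#' `presence_matrix.tsv`, `bins.bed`, and (when fragile sites are supplied)
#' `fragile_overlap.tsv` and `fragile_summary.tsv`, plus a machine-readable
#' `run_manifest.yaml` recording parameters and masked-SNP counts. Outputs
#' are bit-identical across reruns of the same config; stage timings go to
#' stderr only.
#'
#' The reference track is averaged over the manifest's `role == "reference"`
#' samples; log2 ratios and all downstream stages cover every sample,
#' reference panel included. The odds-ratio table contrasts roles
#' `"tumor"` against `"reference" + "control"` (the NMCE pool).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`ratios`,
#'   `segments`, `events`, `bins`, `counts`, `ors`, `top`, `overlap`,
#'   `fragile_summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_inputs(config)
  if (any(issues$severity == "fatal")) {
    abort(paste0("invalid inputs:\n",
                 paste(issues$message[issues$severity == "fatal"],
                       collapse = "\n")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, code) {
    t0 <- Sys.time()
    r <- force(code)
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  mat <- read_intensity_matrix(config$intensities)
  man <- read_manifest(config$manifest)
  lens <- readr::read_tsv(config$chrom_lengths, show_col_types = FALSE,
                          progress = FALSE)

  ref_samples <- man$sample_id[man$role == "reference"]
  if (!length(ref_samples)) abort("stage cnv: no reference-role samples")
  ratios <- stage("cnv", {
    ref <- build_reference(mat, ref_samples)
    suppressMessages(log2_ratio(mat, ref))
  })
  write_intensity_matrix(ratios, out("log2_ratios.tsv"))

  segments <- stage("segment", cbs_segment(ratios, config$seg))
  write_seg(segments, out("segments.seg.tsv"))

  bins <- make_bins(lens, config$bin_size, config$excluded_chroms)
  write_bins_bed(bins, out("bins.bed"))
  events <- stage("breakpoints", call_breakpoints(segments, bins, config$rule))
  readr::write_tsv(events, out("events.tsv"))

  res <- stage("stats", {
    counts <- count_by_bin(events, man, bins)
    roles <- attr(counts, "roles")
    tumor_groups <- names(roles)[roles == "tumor"]
    ors <- if (length(tumor_groups)) or_table(counts) else NULL
    top <- if (length(tumor_groups)) {
      top_regions(counts, tumor_groups, config$top_fraction)
    } else NULL
    pm <- presence_matrix(events, bins, man$sample_id)
    list(counts = counts, ors = ors, top = top, pm = pm)
  })
  readr::write_tsv(as_tibble(res$counts), out("bin_counts.tsv"))
  if (!is.null(res$ors)) readr::write_tsv(res$ors, out("or_table.tsv"))
  if (!is.null(res$top)) readr::write_tsv(res$top, out("top_regions.tsv"))
  readr::write_tsv(res$pm, out("presence_matrix.tsv"))

  overlap <- NULL
  frag_sum <- NULL
  if (!is.null(config$fragile_sites)) {
    overlap <- stage("fragile", {
      sites <- read_fragile_sites(config$fragile_sites,
                                  config$fragile_format)
      overlap_bins(bins, sites)
    })
    hit_bins <- as_tibble(res$counts) %>%
      group_by(.data$bin_id) %>%
      summarise(hit = sum(.data$event_count) > 0) %>%
      filter(.data$hit) %>% pull("bin_id")
    subsets <- list(all_bins = bins$bin_id, breakpoint_bins = hit_bins)
    if (!is.null(res$ors)) {
      subsets$or_below_1 <- res$ors$bin_id[res$ors$bin_id %in% hit_bins &
                                             res$ors$odds_ratio < 1]
      subsets$or_above_1 <- res$ors$bin_id[res$ors$bin_id %in% hit_bins &
                                             res$ors$odds_ratio > 1]
    }
    if (!is.null(res$top)) subsets$top_regions <- res$top$bin_id
    frag_sum <- stratified_fragile_fraction(overlap, subsets)
    readr::write_tsv(overlap, out("fragile_overlap.tsv"))
    readr::write_tsv(frag_sum, out("fragile_summary.tsv"))
  }

  manifest_out <- list(
    package = "cnvbreaks",
    version = as.character(utils::packageVersion("cnvbreaks")),
    parameters = list(
      alpha = config$seg$alpha, min_width = config$seg$min_width,
      undo_sd = config$seg$undo_sd,
      n_permutations = config$seg$n_permutations, seed = config$seg$seed,
      min_delta = config$rule$min_delta,
      major_min_snps = config$rule$major_min_snps,
      minor_min_snps = config$rule$minor_min_snps,
      bin_size = config$bin_size, top_fraction = config$top_fraction,
      excluded_chroms = as.list(config$excluded_chroms)
    ),
    n_reference = length(ref_samples),
    masked_snps = as.list(attr(ratios, "masked_counts")),
    inputs = lapply(
      c(intensities = config$intensities, manifest = config$manifest,
        chrom_lengths = config$chrom_lengths),
      function(p) unname(tools::md5sum(p))
    )
  )
  yaml::write_yaml(manifest_out, out("run_manifest.yaml"))

  invisible(list(
    ratios = ratios, segments = segments, events = events, bins = bins,
    counts = res$counts, ors = res$ors, top = res$top,
    presence = res$pm, overlap = overlap, fragile_summary = frag_sum,
    paths = list.files(config$out_dir, full.names = TRUE)
  ))
}
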