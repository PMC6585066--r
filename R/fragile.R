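#' Read a fragile-site coordinate table
#'
#' Common fragile sites (CFSs, e.g. FRA3B, FRA16D) are consumed as plain
#' coordinate intervals. Two dialects are supported: 4-column BED
#' (`chrom`, `start`, `end`, `name`; 0-based half-open, converted on load)
#' and a headered 1-based inclusive TSV with columns `name`, `chrom`,
#' `start_bp`, `end_bp`.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return Tibble `name`, `chrom`, `start_bp`, `end_bp` (1-based inclusive).
#' @export
read_fragile_sites <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE, progress = FALSE)
    x <- tibble(name = x$name, chrom = as.character(x$chrom),
                start_bp = x$start + 1, end_bp = as.numeric(x$end))
  } else {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("name", "chrom", "start_bp", "end_bp")
    if (!all(need %in% names(x))) {
      abort("fragile-site TSV needs columns name, chrom, start_bp, end_bp")
    }
    x <- mutate(x, chrom = as.character(.data$chrom))
  }
  if (any(x$start_bp > x$end_bp)) abort("inverted fragile-site interval")
  if (anyDuplicated(x$name)) abort("fragile-site names must be unique")
  x
}

#' Overlap bins with fragile sites
#'
#' A bin is associated with a fragile site when their 1-based inclusive
#' intervals share at least `min_overlap` base pairs (default 1 bp — any
#' intersection counts; mere adjacency does not). All overlapping site names
#' are recorded per bin.
#'
#' @param bins Bin tibble from [make_bins()] (any tibble with `bin_id`,
#'   `chrom`, `start_bp`, `end_bp` works).
#' @param sites Fragile-site tibble from [read_fragile_sites()].
#' @param min_overlap Minimum intersection width in bp (>= 1).
#' @return Tibble `bin_id`, `chrom`, `start_bp`, `end_bp`, `n_sites`,
#'   `sites` (comma-joined names, `""` if none), `has_site`.
#' @export
overlap_bins <- function(bins, sites, min_overlap = 1) {
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  site_str <- rep("", nrow(bins))
  n_sites <- integer(nrow(bins))
  for (chr in unique(bins$chrom)) {
    bi <- which(bins$chrom == chr)
    si <- which(sites$chrom == chr)
    if (!length(bi) || !length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(bins$start_bp[bi], bins$end_bp[bi]),
      IRanges::IRanges(sites$start_bp[si], sites$end_bp[si]),
      minoverlap = min_overlap
    )
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (b in unique(qh)) {
      nm <- sites$name[si[sh[qh == b]]]
      site_str[bi[b]] <- paste(nm, collapse = ",")
      n_sites[bi[b]] <- length(nm)
    }
  }
  bins %>%
    select("bin_id", "chrom", "start_bp", "end_bp") %>%
    mutate(n_sites = n_sites, sites = site_str, has_site = n_sites > 0)
}

#' Fragile-site association fraction of bin subsets
#'
#' For each named subset of bins (e.g. "odds ratio > 1", "top-15"), the
#' fraction of its bins overlapping at least one fragile site, raw and as a
#' whole-number percentage. Empty subsets are reported absent (`NA`).
#'
#' @param report Overlap tibble from [overlap_bins()].
#' @param bin_subsets Named list of `bin_id` character vectors.
#' @return Tibble `subset`, `n_bins`, `n_with_site`, `fraction`, `percent`.
#' @export
stratified_fragile_fraction <- function(report, bin_subsets) {
  if (is.null(names(bin_subsets)) || any(!nzchar(names(bin_subsets)))) {
    abort("`bin_subsets` must be a named list")
  }
  purrr::imap(bin_subsets, function(ids, nm) {
    sel <- report[report$bin_id %in% ids, ]
    if (nrow(sel) == 0) {
      return(tibble(subset = nm, n_bins = 0L, n_with_site = NA_integer_,
                    fraction = NA_real_, percent = NA_real_))
    }
    tibble(
      subset = nm, n_bins = nrow(sel),
      n_with_site = sum(sel$has_site),
      fraction = sum(sel$has_site) / nrow(sel),
      percent = round(100 * sum(sel$has_site) / nrow(sel))
    )
  }) %>% bind_rows()
}
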