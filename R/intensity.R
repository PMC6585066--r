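#' Sum per-SNP allele intensities
#'
#' Total copy-number signal for one sample is the elementwise sum of its A and
#' B allele intensities.
#'
#' @param allele_a,allele_b Equal-length numeric vectors of non-negative
#'   allele intensities, SNP-aligned.
#' @return Numeric vector of A+B totals.
#' @export
#' @examples
#' sum_alleles(c(100, 20), c(50, 30))
sum_alleles <- function(allele_a, allele_b) {
  if (length(allele_a) != length(allele_b)) {
    abort("allele vectors must have equal length")
  }
  if (any(allele_a < 0, na.rm = TRUE) || any(allele_b < 0, na.rm = TRUE)) {
    abort("allele intensities must be non-negative")
  }
  allele_a + allele_b
}

snp_key_cols <- c("snp_id", "chrom", "position")

sample_cols_of <- function(intensities, samples = NULL) {
  cand <- setdiff(names(intensities), snp_key_cols)
  if (is.null(samples)) return(cand)
  missing <- setdiff(samples, cand)
  if (length(missing)) {
    abort(paste0("samples absent from matrix: ", paste(missing, collapse = ", ")))
  }
  samples
}

#' Average a reference panel into a reference track
#'
#' The per-SNP reference signal is the arithmetic mean of the reference-panel
#' samples' total intensities; each sample is later expressed as a log2 ratio
#' against it.
#'
#' @param intensities Intensity matrix tibble (`snp_id`, `chrom`, `position`,
#'   one column per sample).
#' @param samples Character vector naming the reference-panel columns
#'   (default: every sample column).
#' @return Tibble `snp_id`, `chrom`, `position`, `ref_mean`, with attribute
#'   `n_reference`.
#' @export
build_reference <- function(intensities, samples = NULL) {
  samples <- sample_cols_of(intensities, samples)
  if (length(samples) == 0) abort("reference panel is empty")
  ref <- intensities %>%
    select(all_of(snp_key_cols)) %>%
    mutate(ref_mean = rowMeans(as.matrix(intensities[samples])))
  attr(ref, "n_reference") <- length(samples)
  ref
}

#' log2 ratios of samples against the reference track
#'
#' Per SNP and sample, `log2(sample / ref_mean)`. SNPs where either the
#' sample or the reference intensity is not strictly positive cannot carry a
#' ratio and are masked (`NA`) rather than clamped; the per-sample masked
#' counts are recorded in the `masked_counts` attribute and reported once via
#' a message.
#'
#' @param intensities Intensity matrix tibble.
#' @param reference Reference track from [build_reference()], SNP-aligned.
#' @param samples Sample columns to convert (default: all).
#' @return Tibble `snp_id`, `chrom`, `position` plus one log2-ratio column
#'   per sample; attributes `masked_counts` (named integer) and
#'   `n_reference`.
#' @export
log2_ratio <- function(intensities, reference, samples = NULL) {
  samples <- sample_cols_of(intensities, samples)
  if (!identical(intensities$snp_id, reference$snp_id)) {
    abort("intensity matrix and reference track are not SNP-aligned")
  }
  ref <- reference$ref_mean
  out <- select(intensities, all_of(snp_key_cols))
  masked <- integer(length(samples))
  names(masked) <- samples
  for (s in samples) {
    x <- intensities[[s]]
    bad <- !(x > 0 & ref > 0) | is.na(x)
    r <- rep(NA_real_, length(x))
    r[!bad] <- log2(x[!bad] / ref[!bad])
    masked[[s]] <- sum(bad)
    out[[s]] <- r
  }
  if (all(masked == nrow(out))) abort("all SNPs masked; no usable ratios")
  if (any(masked > 0)) {
    message(sum(masked), " SNP value(s) masked (non-positive intensity)")
  }
  attr(out, "masked_counts") <- masked
  attr(out, "n_reference") <- attr(reference, "n_reference")
  out
}

#' Read / write the SNP-keyed TSV matrix dialect
#'
#' Tab-separated with header: columns `snp_id`, `chrom`, `position`, then one
#' numeric column per sample. Used for both intensity matrices and log2-ratio
#' tracks (masked ratios are written as `NA`).
#'
#' @param path File path.
#' @return A tibble in the matrix layout.
#' @export
read_intensity_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(snp_key_cols %in% names(x))) {
    abort("matrix file must have snp_id, chrom, position columns")
  }
  mutate(x, chrom = as.character(.data$chrom))
}

#' @param x Matrix tibble to write.
#' @rdname read_intensity_matrix
#' @export
write_intensity_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a sample manifest
#'
#' Two- or three-column TSV: `sample_id`, `group`, optional `role`. When
#' `role` is absent it defaults to the group name.
#'
#' @param path File path.
#' @return Tibble `sample_id`, `group`, `role`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(m))) {
    abort("manifest must have sample_id and group columns")
  }
  if (!"role" %in% names(m)) m$role <- m$group
  select(m, "sample_id", "group", "role")
}
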