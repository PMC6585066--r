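#' SNP coordinate maps
#'
#' A `snp_map` ties every downstream matrix to a shared per-SNP coordinate
#' system: an ordered table of SNP identifiers with chromosome and 1-based
#' position, plus the chromosome lengths the positions live in. All intensity
#' matrices, log2-ratio tracks and truth tables produced by the package are
#' keyed to one such map.
#'
#' @param snps A data frame with columns `snp_id`, `chrom`, `position`
#'   (1-based base pairs), sorted by chromosome then position.
#' @param chrom_lengths A data frame with columns `chrom` and `length`
#'   (base pairs), or a named numeric vector.
#'
#' @return An object of class `snp_map`: a list with tibbles `$snps` and
#'   `$chrom_lengths`.
#' @export
#' @examples
#' snp_map(
#'   data.frame(snp_id = c("s1", "s2"), chrom = "chrA", position = c(10, 20)),
#'   c(chrA = 100)
#' )
snp_map <- function(snps, chrom_lengths) {
  snps <- as_tibble(snps)
  if (!all(c("snp_id", "chrom", "position") %in% names(snps))) {
    abort("`snps` needs columns snp_id, chrom, position")
  }
  chrom_lengths <- as_chrom_lengths(chrom_lengths)
  snps <- mutate(snps,
    snp_id = as.character(.data$snp_id),
    chrom = as.character(.data$chrom),
    position = as.numeric(.data$position)
  )
  if (anyDuplicated(snps$snp_id)) abort("snp_ids must be unique")
  missing_chr <- setdiff(unique(snps$chrom), chrom_lengths$chrom)
  if (length(missing_chr)) {
    abort(paste0("chromosomes absent from length table: ",
                 paste(missing_chr, collapse = ", ")))
  }
  chk <- snps %>%
    left_join(chrom_lengths, by = "chrom") %>%
    group_by(.data$chrom) %>%
    summarise(
      sorted = !is.unsorted(.data$position, strictly = TRUE),
      in_range = all(.data$position >= 1 & .data$position <= .data$length)
    )
  if (!all(chk$sorted)) {
    abort("positions must be strictly increasing within each chromosome")
  }
  if (!all(chk$in_range)) abort("positions must lie within [1, chrom length]")
  structure(
    list(snps = snps, chrom_lengths = chrom_lengths),
    class = "snp_map"
  )
}

as_chrom_lengths <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble(chrom = names(x), length = unname(x))
  }
  x <- as_tibble(x)
  if (!all(c("chrom", "length") %in% names(x))) {
    abort("chromosome lengths need columns chrom and length")
  }
  x <- mutate(x, chrom = as.character(.data$chrom),
              length = as.numeric(.data$length))
  if (anyDuplicated(x$chrom)) abort("duplicate chromosome names")
  if (any(x$length < 1)) abort("chromosome lengths must be >= 1")
  x
}

#' @export
print.snp_map <- function(x, ...) {
  cat("<snp_map> ", nrow(x$snps), " SNPs on ",
      nrow(x$chrom_lengths), " chromosome(s)\n", sep = "")
  print(x$chrom_lengths, ...)
  invisible(x)
}

#' Simulate a SNP map
#'
#' Draws, for each chromosome, a fixed number of distinct SNP positions
#' uniformly without replacement and returns them sorted. Deterministic for a
#' given seed.
#'
#' @param chrom_lengths Named numeric vector or two-column data frame
#'   (`chrom`, `length`) of chromosome lengths in base pairs.
#' @param snps_per_chrom Number of SNPs per chromosome; either a single count
#'   applied to every chromosome or a vector named by chromosome. Must be at
#'   least 2 and no larger than the chromosome length.
#' @param seed Integer seed.
#'
#' @return A [snp_map].
#' @export
#' @examples
#' make_snp_map(c(chrA = 1e6, chrB = 5e5), 50, seed = 1)
make_snp_map <- function(chrom_lengths, snps_per_chrom, seed) {
  chrom_lengths <- as_chrom_lengths(chrom_lengths)
  n_chr <- nrow(chrom_lengths)
  if (length(snps_per_chrom) == 1L && is.null(names(snps_per_chrom))) {
    snps_per_chrom <- setNames(rep(snps_per_chrom, n_chr), chrom_lengths$chrom)
  }
  if (!all(chrom_lengths$chrom %in% names(snps_per_chrom))) {
    abort("snps_per_chrom must cover every chromosome")
  }
  n_snp <- snps_per_chrom[chrom_lengths$chrom]
  if (any(n_snp < 2)) abort("need at least 2 SNPs per chromosome")
  if (any(n_snp > chrom_lengths$length)) {
    abort("snps_per_chrom exceeds chromosome length")
  }
  snps <- with_seed(seed, {
    purrr::map2(chrom_lengths$chrom, seq_len(n_chr), function(chr, i) {
      len <- chrom_lengths$length[i]
      k <- n_snp[[chr]]
      pos <- sort(sample.int(len, k, replace = FALSE))
      tibble(
        snp_id = sprintf("%s_snp%06d", chr, seq_len(k)),
        chrom = chr,
        position = as.numeric(pos)
      )
    }) %>% bind_rows()
  })
  snp_map(snps, chrom_lengths)
}

# Run code under a local RNG state; restores the caller's state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stable per-index substream seed: adding samples must not reshuffle
# earlier ones. Knuth-style multiplicative hash folded into [0, 2^31 - 2].
substream_seed <- function(seed, index) {
  h <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 16807
  as.integer(h %% 2147483646) + 1L
}
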