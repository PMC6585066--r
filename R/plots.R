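#' Plot a sample's log2-ratio track with its segmentation
#'
#' Per-SNP log2 ratios as points, overlaid with the fitted segment means.
#'
#' @param ratios log2-ratio matrix tibble.
#' @param segments Segment tibble ([cbs_segment()] output), may be `NULL`.
#' @param sample Sample column to draw.
#' @param chroms Chromosomes to include (default: all).
#' @return A ggplot object.
#' @export
plot_log2_track <- function(ratios, segments = NULL, sample,
                            chroms = NULL) {
  df <- tibble(
    chrom = ratios$chrom, position = ratios$position,
    log2_ratio = ratios[[sample]]
  ) %>% filter(!is.na(.data$log2_ratio))
  if (!is.null(chroms)) df <- filter(df, .data$chrom %in% chroms)
  p <- ggplot2::ggplot(df,
                       ggplot2::aes(.data$position, .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "darkgreen") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log2 ratio", title = sample) +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    seg <- as_tibble(segments) %>% filter(.data$sample_id == sample)
    if (!is.null(chroms)) seg <- filter(seg, .data$chrom %in% chroms)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_bp, xend = .data$end_bp,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "red", linewidth = 1
    )
  }
  p
}

#' @export
autoplot.cbs_segmentation <- function(object, sample = NULL, ...) {
  seg <- as_tibble(object)
  if (is.null(sample)) sample <- seg$sample_id[1]
  seg <- filter(seg, .data$sample_id == !!sample)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_bp, xend = .data$end_bp,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "red", linewidth = 1
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "segment mean log2 ratio",
                  title = sample) +
    ggplot2::theme_minimal()
}

#' Heat-map style view of the breakpoint presence matrix
#'
#' @param pm Presence matrix from [presence_matrix()].
#' @param drop_empty Drop bins no sample hits (default TRUE).
#' @return A ggplot object.
#' @export
plot_presence_matrix <- function(pm, drop_empty = TRUE) {
  long <- tidyr::pivot_longer(pm, -c("bin_id", "chrom", "start_bp"),
                              names_to = "sample_id", values_to = "present")
  if (drop_empty) {
    keep <- long %>% group_by(.data$bin_id) %>%
      summarise(any = sum(.data$present) > 0) %>%
      filter(.data$any) %>% pull("bin_id")
    long <- filter(long, .data$bin_id %in% keep)
  }
  long <- mutate(long, bin_id = factor(.data$bin_id, levels = pm$bin_id))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$bin_id,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "steelblue"),
                               name = "breakpoint") +
    ggplot2::labs(x = "sample", y = "100 kb bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Per-bin recurrence barplot for one group
#'
#' @param counts A [count_by_bin()] table.
#' @param group Group name.
#' @param min_count Only bins with at least this many samples (default 1).
#' @return A ggplot object.
#' @export
plot_bin_recurrence <- function(counts, group, min_count = 1) {
  df <- as_tibble(counts) %>%
    filter(.data$group == !!group, .data$sample_count >= min_count)
  ggplot2::ggplot(df, ggplot2::aes(.data$start_bp, .data$sample_count)) +
    ggplot2::geom_col(width = 9e4, fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "bin start (bp)", y = "samples with breakpoint",
                  title = group) +
    ggplot2::theme_minimal()
}
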