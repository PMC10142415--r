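#' Quadrant scatterplot of hash counts for two samples
#'
#' Log-scale scatter of per-nucleus hash counts for a pair of samples, the
#' standard diagnostic for cutoff-based demultiplexing: singlets sit along
#' the axes, multiplets in the upper-right quadrant, negatives near the
#' origin. Dashed lines mark the cutoffs when supplied.
#'
#' @param counts a `hash_count_matrix`, matrix, or long tibble.
#' @param cutoffs optional [auto_cutoff()] tibble or named vector.
#' @param samples which two samples to plot (default: the first two
#'   columns).
#' @return a ggplot object.
#' @export
plot_hash_scatter <- function(counts, cutoffs = NULL, samples = NULL) {
  m <- as_count_matrix(counts)
  if (is.null(samples)) samples <- colnames(m)[1:2]
  stopifnot(length(samples) == 2)
  df <- tibble(x = m[, samples[1]], y = m[, samples[2]])
  if (!is.null(cutoffs)) {
    cut <- cutoff_vector(cutoffs, samples)
    df$quadrant <- dplyr::case_when(
      df$x >= cut[1] & df$y >= cut[2] ~ "multiplet",
      df$x >= cut[1] ~ samples[1],
      df$y >= cut[2] ~ samples[2],
      TRUE ~ "negative"
    )
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x + 1, y = .data$y + 1)) +
    ggplot2::geom_point(
      if (!is.null(cutoffs)) ggplot2::aes(colour = .data$quadrant) else NULL,
      size = 0.6, alpha = 0.6
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste(samples[1], "hash count + 1"),
                  y = paste(samples[2], "hash count + 1"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    cut <- cutoff_vector(cutoffs, samples)
    p <- p +
      ggplot2::geom_vline(xintercept = cut[1], linetype = "dashed") +
      ggplot2::geom_hline(yintercept = cut[2], linetype = "dashed")
  }
  p
}

#' Barnyard plot: per-genome fragment counts coloured by hash call
#'
#' @param genome_counts long tibble (`cell_barcode`, `genome_id`,
#'   `fragment_count`) with exactly two genomes.
#' @param hash_calls optional calls tibble from [classify_hash()] to colour
#'   the points.
#' @return a ggplot object.
#' @export
plot_barnyard <- function(genome_counts, hash_calls = NULL) {
  genomes <- sort(unique(genome_counts$genome_id))
  stopifnot(length(genomes) == 2)
  wide <- tidyr::pivot_wider(genome_counts, names_from = "genome_id",
                             values_from = "fragment_count",
                             values_fill = 0L)
  if (!is.null(hash_calls)) {
    wide <- dplyr::left_join(wide, hash_calls[, c("cell_barcode", "label")],
                             by = "cell_barcode")
  }
  p <- ggplot2::ggplot(wide, ggplot2::aes(
    x = .data[[genomes[1]]] + 1, y = .data[[genomes[2]]] + 1
  )) +
    ggplot2::geom_point(
      if (!is.null(hash_calls)) ggplot2::aes(colour = .data$label) else NULL,
      size = 0.6, alpha = 0.6
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste(genomes[1], "fragments + 1"),
                  y = paste(genomes[2], "fragments + 1"),
                  colour = "hash call") +
    ggplot2::theme_minimal()
  p
}

#' Histogram of a dichotomized intensity distribution
#'
#' @param object an `intensity_split` from [dichotomize_intensity()].
#' @param scores the score vector the split was computed on.
#' @param ... unused.
#' @return a ggplot object (log-scale histogram with the threshold marked).
#' @exportS3Method
autoplot.intensity_split <- function(object, scores, ...) {
  df <- tibble(score = scores, group = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8, position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "bulk peak intensity", y = "peaks", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bulk intensity by cluster-presence count
#'
#' @param records a tibble with `cnum` and `bulk_score` columns (e.g.
#'   [assign_cnum()] then [attach_bulk()]); rows without a bulk score are
#'   dropped.
#' @return a ggplot boxplot of log bulk intensity by cnum group.
#' @export
plot_cnum_intensity <- function(records) {
  df <- dplyr::filter(records, !is.na(.data$bulk_score))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cnum),
                                   y = .data$bulk_score)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clusters containing the peak (cnum)",
                  y = "bulk peak intensity") +
    ggplot2::theme_minimal()
}
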