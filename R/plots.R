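#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome-wide methylation scatter profile
#'
#' One point per fixed window: Watson-strand MDs plotted upward, Crick-strand
#' MDs mirrored downward, against genomic position.
#'
#' @param profile Tibble from [fixed_window_profile()].
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profile) {
  dat <- dplyr::mutate(
    profile,
    signed_md = ifelse(.data$strand == "C", -.data$md, .data$md),
    strand_lab = ifelse(.data$strand == "C", "Crick", "Watson")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$window_start,
                                    y = .data$signed_md,
                                    colour = .data$strand_lab,
                                    shape = .data$strand_lab)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(Watson = 16, Crick = 17)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "MD (%)  [Crick mirrored]",
                  colour = "strand", shape = "strand") +
    ggplot2::theme_minimal()
}

#' Methylation density per trinucleotide context
#'
#' @param spectrum Output of [context_spectrum()] (the list or its
#'   `contexts` tibble).
#' @return A ggplot object.
#' @export
plot_context_spectrum <- function(spectrum) {
  dat <- if (is.data.frame(spectrum)) spectrum else spectrum$contexts
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$context3, y = .data$md,
                                    fill = .data$context_class)) +
    ggplot2::geom_col(na.rm = TRUE) +
    ggplot2::labs(x = "context", y = "MD (%)", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Base composition per sequencing cycle
#'
#' @param comp Tibble from [per_cycle_composition()].
#' @return A ggplot object.
#' @export
plot_cycle_composition <- function(comp) {
  long <- tidyr::pivot_longer(comp, c("fA", "fC", "fG", "fT"),
                              names_to = "base", values_to = "fraction") |>
    dplyr::mutate(base = sub("^f", "", .data$base))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$fraction,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "base fraction", colour = "base") +
    ggplot2::theme_minimal()
}

#' Insert size distribution plot
#'
#' @param hist Tibble from [insert_size_distribution()].
#' @return A ggplot object.
#' @export
plot_insert_sizes <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$insert_size,
                                     y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "insert size (bp)", y = "fragments") +
    ggplot2::theme_minimal()
}

#' Sequencing-versus-array concordance scatter
#'
#' @param concordance Output of [correlate_with_array()].
#' @return A ggplot object.
#' @export
plot_array_concordance <- function(concordance) {
  ggplot2::ggplot(concordance$data,
                  ggplot2::aes(x = .data$beta, y = .data$md_fraction)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "array beta", y = "sequencing MD (fraction)",
      subtitle = sprintf("Pearson r = %.3f over %d loci",
                         concordance$pearson_r, concordance$n_loci)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bsm_dmr_result <- function(object, ...) {
  d <- object$dmrs
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$md2 - .data$md1,
                                  colour = .data$direction)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$md2 - .data$md1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "MD difference (B - A, %)") +
    ggplot2::theme_minimal()
}
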