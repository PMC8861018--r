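#' Plot a substitution spectrum
#'
#' Bar chart of class proportions, in canonical class order.
#'
#' @param object A `spectrum_table` from [build_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_table
#' @export
autoplot.spectrum_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      class = factor(.data$class,
                                     levels = substitution_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Proportion of DNMs",
                  title = "Substitution spectrum") +
    ggplot2::theme_minimal()
}

#' Plot window mutation counts from a hotspot fit
#'
#' Per-window counts along the genome with the hotspot threshold line.
#'
#' @param object A `hotspot_fit` from [poisson_hotspot_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hotspot_fit
#' @export
autoplot.hotspot_fit <- function(object, ...) {
  df <- tibble::as_tibble(object$windows)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$count,
                                   fill = .data$hotspot)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$hotspot_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "Window (genome order)", y = "DNM count",
                  title = "DNMs per genomic window") +
    ggplot2::theme_minimal()
}

#' Histogram of DNM variant allele fractions
#'
#' The two timing classes concentrate near 0.5 (2:2) and 0.25 (1:3); the
#' class interval boundaries are drawn as dashed lines.
#'
#' @param dnms DNM tibble with `vaf` (and optionally `genotype_class`).
#' @param rule A [genotype_rule()] supplying the boundary lines.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_vaf_distribution <- function(dnms, rule = genotype_rule(),
                                  binwidth = 0.02) {
  if (!"genotype_class" %in% names(dnms)) {
    dnms <- dplyr::mutate(dnms,
                          genotype_class = classify_genotype(.data$vaf, rule))
  }
  ggplot2::ggplot(dnms, ggplot2::aes(x = .data$vaf,
                                     fill = .data$genotype_class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(rule$lo_13, rule$lo_11, rule$hi_11),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Variant allele fraction", y = "DNMs",
                  fill = "Timing class",
                  title = "Observed VAF of called DNMs") +
    ggplot2::theme_minimal()
}

#' Per-sample DNM counts by group
#'
#' @param counts A `dnm_counts` object from [count_dnms_by_sample()].
#' @return A ggplot object.
#' @export
plot_dnm_counts <- function(counts) {
  stopifnot(inherits(counts, "dnm_counts"))
  ggplot2::ggplot(counts$per_sample,
                  ggplot2::aes(x = .data$sibship_id, y = .data$n_dnms,
                               colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "grey20") +
    ggplot2::labs(x = "Sibship", y = "DNMs per sample", colour = "Group",
                  title = "Per-sample DNM counts") +
    ggplot2::theme_minimal()
}
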