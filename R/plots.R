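#' Plot the score distribution of a screening run
#'
#' Histogram of chimera scores on a log10 axis with the flagging
#' threshold marked; the standard first look at whether flagged and
#' unflagged queries separate cleanly.
#'
#' @param object A `"chimera_screen"` tibble from [screen_corpus()].
#' @param bins Number of histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.chimera_screen <- function(object, bins = 40, ...) {
  params <- attr(object, "params", exact = TRUE)
  threshold <- params$threshold %||% 0.28
  df <- as_tibble(object)
  # scores of 0 (no two-parent evidence) cannot sit on a log axis
  df$plot_score <- pmax(df$score, threshold / 100)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plot_score,
                                   fill = .data$flag)) +
    ggplot2::geom_histogram(bins = bins, colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#b2182b"),
                               name = "flagged") +
    ggplot2::labs(x = "chimera score (log scale)", y = "queries",
                  title = "Chimera score distribution",
                  subtitle = sprintf("threshold %.2f; %d of %d flagged",
                                     threshold, sum(df$flag), nrow(df)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-replicate detection rates
#'
#' @param stats A [detection_stats()] object.
#' @return A ggplot object: one point per replicate with the mean as a
#'   horizontal line.
#' @export
plot_detection_rates <- function(stats) {
  stopifnot(inherits(stats, "detection_stats"))
  ggplot2::ggplot(stats$rates,
                  ggplot2::aes(x = factor(.data$replicate),
                               y = .data$rate_pct)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = stats$mean_pct, linetype = "dashed",
                        colour = "#2166ac") +
    ggplot2::labs(x = "replicate", y = "chimeras detected (%)",
                  title = "Benchmark detection rate per replicate",
                  subtitle = sprintf("mean %.2f%%", stats$mean_pct))
}

#' Compare score distributions of two groups graphically
#'
#' Boxplots of chimera scores for two labelled groups (e.g. simulated
#' chimeras vs clean references) on a log10 axis.
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param labels Group labels (length 2).
#' @param floor Scores at or below 0 are drawn at this value so they can
#'   sit on the log axis (default 1e-3).
#' @return A ggplot object.
#' @export
plot_score_groups <- function(scores_a, scores_b,
                              labels = c("chimeric", "non-chimeric"),
                              floor = 1e-3) {
  df <- tibble(group = rep(labels, c(length(scores_a), length(scores_b))),
               score = pmax(c(scores_a, scores_b), floor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "chimera score (log scale)",
                  title = "Chimera scores by group")
}
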