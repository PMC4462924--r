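#' Detection statistics across benchmark replicates
#'
#' Per-replicate flagged fractions and their mean and sample standard
#' deviation (n - 1 denominator), reported as percentages.
#'
#' @param calls A call tibble with a `replicate` column and logical
#'   `flag` (e.g. replicate-wise [screen_corpus()] results bound
#'   together).
#' @return An object of class `"detection_stats"`: a list with `rates`
#'   (tibble: `replicate`, `n`, `n_flagged`, `rate_pct`), `mean_pct` and
#'   `sd_pct` (`NA` for a single replicate). Has [tidy()] and [glance()]
#'   methods.
#' @export
detection_stats <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("replicate", "flag") %in% names(calls)))
  if (nrow(calls) == 0L) stop("no calls supplied", call. = FALSE)
  rates <- calls |>
    group_by(.data$replicate) |>
    summarise(n = n(), n_flagged = sum(.data$flag), .groups = "drop") |>
    mutate(rate_pct = 100 * .data$n_flagged / .data$n)
  structure(list(rates = rates,
                 mean_pct = mean(rates$rate_pct),
                 sd_pct = if (nrow(rates) > 1L) sd(rates$rate_pct) else
                   NA_real_),
            class = "detection_stats")
}

#' @export
print.detection_stats <- function(x, ...) {
  cat(sprintf("Chimera detection over %d replicate(s): mean %.2f%% (SD %s)\n",
              nrow(x$rates), x$mean_pct,
              ifelse(is.na(x$sd_pct), "NA", sprintf("%.4f", x$sd_pct))))
  invisible(x)
}

#' @rdname detection_stats
#' @param x A `"detection_stats"` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.detection_stats <- function(x, ...) x$rates

#' @rdname detection_stats
#' @exportS3Method generics::glance
glance.detection_stats <- function(x, ...) {
  tibble(n_replicates = nrow(x$rates), n_total = sum(x$rates$n),
         mean_pct = x$mean_pct, sd_pct = x$sd_pct)
}

#' Summary of a screening run
#'
#' @param x A `"chimera_screen"` tibble from [screen_corpus()].
#' @param ... Unused.
#' @return One row: query count, flagged count and fraction, threshold.
#' @exportS3Method generics::glance
glance.chimera_screen <- function(x, ...) {
  params <- attr(x, "params", exact = TRUE)
  tibble(n_queries = nrow(x), n_flagged = sum(x$flag),
         flagged_frac = if (nrow(x)) mean(x$flag) else NA_real_,
         threshold = params$threshold %||% NA_real_)
}

#' Bin flagged chimera scores
#'
#' Counts flagged calls in the conventional reporting bins: above the
#' threshold but at most 1, above 1 up to 10, and above 10. Bins are
#' left-open and right-closed, so they partition the flagged set exactly
#' (assuming `threshold < 1`).
#'
#' @param calls A call tibble with `score` and logical `flag`.
#' @param threshold Score threshold in force when `flag` was set
#'   (default 0.28).
#' @return A tibble with columns `bin` and `n` (three rows).
#' @export
bin_scores <- function(calls, threshold = 0.28) {
  stopifnot(is.data.frame(calls), all(c("score", "flag") %in% names(calls)))
  s <- calls$score[calls$flag]
  tibble(
    bin = c(sprintf("(%g,1]", threshold), "(1,10]", "(10,Inf)"),
    n = c(sum(s > threshold & s <= 1), sum(s > 1 & s <= 10), sum(s > 10))
  )
}

#' Compare score distributions of two groups
#'
#' Wilcoxon-Mann-Whitney rank-sum test (midranks for ties, normal
#' approximation with tie-corrected variance and continuity correction),
#' with group medians reported alongside. Used to contrast chimeric vs
#' non-chimeric score distributions.
#'
#' @param scores_a,scores_b Non-empty numeric score vectors.
#' @return A one-row tibble: `median_a`, `median_b`, `statistic`
#'   (the Mann-Whitney U for group a), `p_value` (two-sided).
#' @export
compare_score_groups <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  wt <- wilcox.test(scores_a, scores_b, exact = FALSE, correct = TRUE)
  tibble(median_a = median(scores_a), median_b = median(scores_b),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Write a benchmark report
#'
#' Writes a human-readable text report (`<path>.txt`) and a
#' machine-readable long-format TSV (`<path>.tsv`, columns `metric`,
#' `value` with 6-decimal values). Byte-identical across reruns on the
#' same inputs: no timestamps are embedded.
#'
#' @param stats A [detection_stats()] object.
#' @param bins A [bin_scores()] tibble.
#' @param comparison A [compare_score_groups()] row.
#' @param path Output path without extension.
#' @param params Optional [detector_params()] echoed for reproducibility.
#' @param seed Optional seed echoed for reproducibility.
#' @return `path`, invisibly.
#' @export
report_benchmark <- function(stats, bins, comparison, path,
                             params = NULL, seed = NULL) {
  stopifnot(inherits(stats, "detection_stats"))
  txt <- c("Chimera benchmark report",
           "========================",
           sprintf("replicates: %d", nrow(stats$rates)),
           sprintf("mean detection: %.4f%%", stats$mean_pct),
           sprintf("sd detection: %s",
                   ifelse(is.na(stats$sd_pct), "NA",
                          sprintf("%.4f", stats$sd_pct))),
           "",
           "score bins (flagged calls):",
           sprintf("  %-10s %d", bins$bin, bins$n),
           "",
           sprintf("median score (group a): %.6f", comparison$median_a),
           sprintf("median score (group b): %.6f", comparison$median_b),
           sprintf("rank-sum statistic: %.6f", comparison$statistic),
           sprintf("two-sided p: %.6g", comparison$p_value))
  if (!is.null(seed)) txt <- c(txt, "", sprintf("seed: %d", seed))
  if (!is.null(params)) {
    txt <- c(txt, "", "detector parameters:",
             sprintf("  %s: %s", names(params),
                     vapply(params, format, character(1))))
  }
  writeLines(txt, paste0(path, ".txt"))
  long <- tibble(
    metric = c("n_replicates", "mean_pct", "sd_pct",
               paste0("bin_", seq_len(nrow(bins))),
               "median_a", "median_b", "statistic", "p_value"),
    value = sprintf("%.6f",
                    c(nrow(stats$rates), stats$mean_pct, stats$sd_pct,
                      bins$n, comparison$median_a, comparison$median_b,
                      comparison$statistic, comparison$p_value))
  )
  readr::write_tsv(long, paste0(path, ".tsv"))
  invisible(path)
}
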