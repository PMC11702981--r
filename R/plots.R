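#' Plot composite scores by sample group
#'
#' Boxplots of each of the seven composite expression scores, split by
#' sample group, mirroring the standard NT / WT / MM / TM panels.
#'
#' @param object A CES tibble from [build_ces_table()].
#' @param groups Named group vector or a sample sheet tibble (`sample`,
#'   `group`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.p53_ces <- function(object, groups, ...) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample)
  }
  long <- object |>
    mutate(group = factor(groups[.data$sample],
                          levels = c("NT", "WT", "MM", "TM"))) |>
    tidyr::pivot_longer(dplyr::all_of(ces_feature_names()),
                        names_to = "score", values_to = "value") |>
    mutate(score = factor(.data$score, levels = ces_feature_names()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "composite expression score") +
    ggplot2::theme_minimal()
}

#' Plot hold-out validation metrics
#'
#' One point per repeat for recall, precision, accuracy, F1 and AUROC,
#' with the per-metric mean marked.
#'
#' @param object A `p53_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.p53_validation <- function(object, ...) {
  long <- object$metrics |>
    tidyr::pivot_longer(c("recall", "precision", "accuracy", "f1", "auroc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "red") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "hold-out metric") +
    ggplot2::theme_minimal()
}

#' Plot the survival-ratio distribution with the responder cutoff
#'
#' Histogram of RT/placebo median-survival ratios with the kernel-density
#' changing point (or a supplied cutoff) marked.
#'
#' @param ratios Numeric survival ratios.
#' @param cutoff Cutoff to mark (default: [find_cutoff()] of `ratios`).
#' @return A ggplot object.
#' @export
plot_survival_ratios <- function(ratios, cutoff = find_cutoff(ratios)) {
  df <- tibble(ratio = ratios)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "median survival ratio (RT / placebo)",
                  y = "PDX models",
                  subtitle = paste0("responder cutoff = ",
                                    signif(cutoff, 3))) +
    ggplot2::theme_minimal()
}
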