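#' Plot per-target metric distributions by method
#'
#' Strip/box view of per-target metric values per method, methods ordered
#' by increasing median — the conventional benchmark figure for comparing
#' scoring methods on AUC or NEF1%.
#'
#' @param results Per-target metric results ([evaluate_screen()]).
#' @param metric Metric to display.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(results, metric = "nef") {
  res <- results[results$metric == metric, ]
  ord <- res |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(m = median(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$m)
  res$method <- factor(res$method, levels = ord$method)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot good-pose fractions at ranks with the sampling ceiling
#'
#' @param pose_eval Output of [good_pose_fraction()]; may carry a `ceiling`
#'   column or attribute from [run_evaluation()].
#' @param ceiling Optional sampling ceiling ([sampling_ceiling()]).
#' @return A ggplot object.
#' @export
plot_pose_rank_success <- function(pose_eval, ceiling = NULL) {
  p <- ggplot2::ggplot(pose_eval,
    ggplot2::aes(x = factor(.data$rank), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue",
      position = ggplot2::position_dodge()) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "pose rank", y = "fraction with good pose") +
    ggplot2::theme_minimal()
  if ("channel" %in% names(pose_eval)) {
    p <- p + ggplot2::aes(fill = .data$channel) +
      ggplot2::scale_fill_brewer(palette = "Set2")
  }
  ceiling <- ceiling %||% pose_eval$ceiling[1]
  if (!is.null(ceiling) && is.finite(ceiling)) {
    p <- p + ggplot2::geom_hline(yintercept = ceiling, linetype = "dashed")
  }
  p
}

#' Plot best-pose versus worst-pose enrichment (pose sensitivity)
#'
#' Per-target early enrichment under best-pose and worst-pose aggregation,
#' each panel sorted by its own values: a pose-sensitive method shows clear
#' separation between the two.
#'
#' @param results Per-target metric results containing methods suffixed
#'   `.best_pose` and `.worst_pose`.
#' @param metric Metric to display (default `"nef"`).
#' @return A ggplot object.
#' @export
plot_pose_sensitivity <- function(results, metric = "nef") {
  res <- results[results$metric == metric &
    grepl("\\.(best_pose|worst_pose)$", results$method), ]
  res$protocol <- sub("^.*\\.", "", res$method)
  res$channel <- sub("\\.(best_pose|worst_pose)$", "", res$method)
  res <- res |>
    dplyr::group_by(.data$channel, .data$protocol) |>
    dplyr::arrange(.data$value, .by_group = TRUE) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(res,
    ggplot2::aes(x = .data$idx, y = .data$value, color = .data$protocol)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "targets (sorted per protocol)", y = toupper(metric),
      color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training-similarity versus enrichment correlation
#'
#' @param similarity Tibble `target`, `similarity`.
#' @param performance Tibble `target`, `value`.
#' @return A ggplot object annotated with Spearman rho and p.
#' @export
plot_similarity_correlation <- function(similarity, performance) {
  merged <- dplyr::inner_join(similarity, performance, by = "target")
  ct <- similarity_performance_correlation(similarity, performance)
  ggplot2::ggplot(merged,
    ggplot2::aes(x = .data$similarity, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.5, color = "grey40") +
    ggplot2::labs(
      x = "avg max Tanimoto similarity to training set",
      y = "early enrichment",
      subtitle = sprintf("Spearman rho = %.2f, p = %.3g", ct$rho, ct$p_value)
    ) +
    ggplot2::theme_minimal()
}
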