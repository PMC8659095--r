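#' Aggregate per-pose scores to one prediction per compound
#'
#' A scoring method produces many scores per compound: one per pose per
#' receptor. The screening protocol reduces them to a single prediction per
#' (target, compound). `aggregate_best()` takes the maximum canonicalized
#' score over all poses and receptors — the standard protocol, matching how
#' multi-receptor screens take the best score over every docked template.
#' `aggregate_worst()` takes the minimum instead; contrasting the two
#' diagnoses pose sensitivity: a method whose worst-pose ranking still
#' enriches actives is drawing on ligand-only information.
#'
#' Compounds that carry a label but no pose (listed in `all_compounds`) are
#' ranked last (`-Inf`) with a warning — the conservative screening
#' interpretation of a failed docking.
#'
#' @param table A `screen_tbl`.
#' @param channel Name of a score channel present in `table`.
#' @param all_compounds Optional tibble with columns `target`, `compound`,
#'   `label` enumerating every compound that should receive a prediction.
#' @param method Label for the `method` column; defaults to
#'   `"<channel>.best_pose"` / `"<channel>.worst_pose"`.
#' @return Tibble with one row per (target, compound): columns `target`,
#'   `compound`, `label`, `method`, `value`.
#' @export
aggregate_best <- function(table, channel, all_compounds = NULL, method = NULL) {
  aggregate_poses(table, channel, max, method %||% paste0(channel, ".best_pose"),
    all_compounds)
}

#' @rdname aggregate_best
#' @export
aggregate_worst <- function(table, channel, all_compounds = NULL, method = NULL) {
  aggregate_poses(table, channel, min, method %||% paste0(channel, ".worst_pose"),
    all_compounds)
}

aggregate_poses <- function(table, channel, f, method, all_compounds = NULL) {
  check_channel(table, channel)
  out <- table |>
    dplyr::group_by(.data$target, .data$compound, .data$label) |>
    dplyr::summarise(value = f(.data[[channel]]), .groups = "drop") |>
    dplyr::mutate(method = method, .before = "value")
  if (!is.null(all_compounds)) {
    missing <- dplyr::anti_join(
      as_tibble(all_compounds)[, c("target", "compound", "label")],
      out, by = c("target", "compound"))
    if (nrow(missing) > 0) {
      warn(glue::glue(
        "{nrow(missing)} labelled compound(s) have no pose; ranked last (-Inf)"
      ))
      missing$label <- normalize_labels(missing$label)
      missing$method <- method
      missing$value <- -Inf
      out <- dplyr::bind_rows(out, missing)
    }
  }
  dplyr::arrange(out, .data$target, .data$compound)
}

check_channel <- function(table, channel) {
  ch <- screen_channels(table)
  if (!channel %in% ch$channel) {
    abort(glue::glue("unknown channel '{channel}'"),
      class = "screenaudit_schema_error")
  }
  invisible(TRUE)
}

#' Pose-affinity product score
#'
#' Combines a pose probability and a predicted affinity by multiplication,
#' the combination emitted by CNN-scoring docking pipelines as `CNN_VS`. The
#' product is taken per pose (negative affinities are clipped to zero so the
#' product preserves higher-is-better ordering), then aggregated with the
#' best-pose protocol.
#'
#' @param pose_prob Pose probability(ies) in \[0, 1\].
#' @param affinity_pK Predicted affinity(ies) in pK units.
#' @return `pose_prob * pmax(affinity_pK, 0)`, same length as the inputs.
#' @examples
#' product_score(0.5, 6.0) # 3.0
#' @export
product_score <- function(pose_prob, affinity_pK) {
  if (any(!is.finite(pose_prob)) || any(pose_prob < 0 | pose_prob > 1)) {
    abort("pose_prob must lie in [0, 1]", class = "screenaudit_domain_error")
  }
  if (any(!is.finite(affinity_pK))) {
    abort("affinity_pK must be finite", class = "screenaudit_domain_error")
  }
  pose_prob * pmax(affinity_pK, 0)
}

#' @rdname product_score
#' @param table A `screen_tbl` carrying both channels.
#' @param pose_channel,affinity_channel Channel names in `table`.
#' @param all_compounds,method See [aggregate_best()].
#' @return `aggregate_product()` returns per-compound predictions (the
#'   per-pose product, best-pose aggregated).
#' @export
aggregate_product <- function(table, pose_channel, affinity_channel,
                              all_compounds = NULL, method = "cnn_vs") {
  check_channel(table, pose_channel)
  check_channel(table, affinity_channel)
  tmp <- table
  tmp$.product <- product_score(table[[pose_channel]], table[[affinity_channel]])
  ch <- dplyr::bind_rows(screen_channels(table), score_channel(".product"))
  attr(tmp, "channels") <- ch
  aggregate_poses(tmp, ".product", max, method, all_compounds)
}

#' Affinity of the best-scoring pose
#'
#' The second score combination: rather than multiplying, select for each
#' compound the pose (across receptors) with the highest pose score and
#' report that pose's predicted affinity as the compound's prediction. Ties
#' in pose score are broken by lower `pose_rank`, then lexicographic
#' `receptor`, so output is deterministic.
#'
#' @inheritParams aggregate_product
#' @return Tibble of per-compound predictions (`target`, `compound`,
#'   `label`, `method`, `value`).
#' @export
affinity_at_best_pose <- function(table, pose_channel, affinity_channel,
                                  all_compounds = NULL,
                                  method = "affinity_at_best_pose") {
  check_channel(table, pose_channel)
  check_channel(table, affinity_channel)
  if (any(!is.finite(table[[pose_channel]])) ||
      any(!is.finite(table[[affinity_channel]]))) {
    abort("both channels must be present and finite on every pose",
      class = "screenaudit_integrity_error")
  }
  out <- table |>
    dplyr::arrange(.data$target, .data$compound,
      dplyr::desc(.data[[pose_channel]]), .data$pose_rank, .data$receptor) |>
    dplyr::group_by(.data$target, .data$compound, .data$label) |>
    dplyr::summarise(value = .data[[affinity_channel]][1], .groups = "drop") |>
    dplyr::mutate(method = method, .before = "value")
  if (!is.null(all_compounds)) {
    missing <- dplyr::anti_join(
      as_tibble(all_compounds)[, c("target", "compound", "label")],
      out, by = c("target", "compound"))
    if (nrow(missing) > 0) {
      warn(glue::glue(
        "{nrow(missing)} labelled compound(s) have no pose; ranked last (-Inf)"
      ))
      missing$label <- normalize_labels(missing$label)
      missing$method <- method
      missing$value <- -Inf
      out <- dplyr::bind_rows(out, missing)
    }
  }
  dplyr::arrange(out, .data$target, .data$compound)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
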