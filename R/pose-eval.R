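#' Build cross-docking tasks from scored poses
#'
#' Cross-docking evaluates pose ranking under realistic conditions: each
#' crystal ligand is docked into every available template receptor other
#' than its own (non-cognate) structure. Given a pose table with RMSDs and a
#' cognate map (which receptor each ligand came from), this keeps one task
#' per (ligand, non-cognate receptor) pair present in the data.
#'
#' @param poses Tibble/`screen_tbl` with columns `target`, `compound`
#'   (ligand id), `receptor`, `pose_rank`, `rmsd`, plus score channels.
#' @param cognate_map Tibble with columns `compound`, `receptor` giving each
#'   ligand's cognate structure.
#' @return The pose rows belonging to cross-docking tasks, with a `task`
#'   identifier column `"<compound>@<receptor>"`.
#' @export
build_crossdock_tasks <- function(poses, cognate_map) {
  stopifnot(all(c("compound", "receptor") %in% names(cognate_map)))
  if (!"rmsd" %in% names(poses) || anyNA(poses$rmsd)) {
    abort("rmsd must be present on every pose",
      class = "screenaudit_integrity_error")
  }
  missing <- setdiff(unique(poses$compound), cognate_map$compound)
  if (length(missing) > 0) {
    abort(glue::glue(
      "ligand(s) missing from cognate map: ",
      "{paste(head(missing, 5), collapse = ', ')}"
    ), class = "screenaudit_integrity_error")
  }
  cog <- setNames(as.character(cognate_map$receptor),
    as.character(cognate_map$compound))
  out <- poses[poses$receptor != cog[poses$compound], , drop = FALSE]
  out$task <- paste0(out$compound, "@", out$receptor)
  as_tibble(out)
}

#' Fraction of tasks with a good pose among the top-ranked poses
#'
#' For each cross-docking task, ranks the task's poses by a score channel
#' (descending, ties broken by original `pose_rank`) and asks whether any of
#' the top-n poses has RMSD at or below the threshold (2 Angstroms is the
#' conventional "good pose" cutoff). Task successes are averaged within each
#' target first, then across targets, so every target weighs equally
#' regardless of how many ligands or templates it contributes.
#'
#' @param tasks Output of [build_crossdock_tasks()] (or any pose tibble with
#'   a `task` column and `rmsd`).
#' @param channel Score channel used for ranking (canonicalized
#'   higher-is-better).
#' @param ranks Integer ranks at which to evaluate, ascending (default
#'   `c(1, 3, 5)`).
#' @param threshold RMSD cutoff in Angstroms (default 2.0).
#' @return Tibble with columns `rank`, `fraction` (mean over targets), plus
#'   attribute `per_target` with the per-target fractions.
#' @export
good_pose_fraction <- function(tasks, channel, ranks = c(1, 3, 5),
                               threshold = 2.0) {
  stopifnot(threshold > 0, !is.unsorted(ranks), all(ranks >= 1))
  if (!"task" %in% names(tasks)) {
    tasks$task <- paste0(tasks$compound, "@", tasks$receptor)
  }
  first_good <- tasks |>
    dplyr::arrange(.data$target, .data$task,
      dplyr::desc(.data[[channel]]), .data$pose_rank) |>
    dplyr::group_by(.data$target, .data$task) |>
    dplyr::summarise(
      first_good = {
        hit <- which(.data$rmsd <= threshold)
        if (length(hit) == 0) Inf else min(hit)
      },
      .groups = "drop"
    )
  per_target <- purrr::map_dfr(ranks, function(n) {
    first_good |>
      dplyr::group_by(.data$target) |>
      dplyr::summarise(rank = n, fraction = mean(.data$first_good <= n),
        .groups = "drop")
  })
  out <- per_target |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  attr(out, "per_target") <- per_target
  out
}

#' Sampling ceiling: best pose ranking achievable with the sampled poses
#'
#' The fraction of tasks that have at least one pose within the RMSD
#' threshold, regardless of score — what a perfect re-ranker could achieve
#' given the sampled poses. Upper-bounds [good_pose_fraction()] at every
#' rank. Averaged per-target first, like the rank fractions.
#'
#' @inheritParams good_pose_fraction
#' @return A single fraction in \[0, 1\].
#' @export
sampling_ceiling <- function(tasks, threshold = 2.0) {
  if (!"task" %in% names(tasks)) {
    tasks$task <- paste0(tasks$compound, "@", tasks$receptor)
  }
  per_task <- tasks |>
    dplyr::group_by(.data$target, .data$task) |>
    dplyr::summarise(any_good = any(.data$rmsd <= threshold), .groups = "drop")
  per_target <- per_task |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(frac = mean(.data$any_good), .groups = "drop")
  mean(per_target$frac)
}
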