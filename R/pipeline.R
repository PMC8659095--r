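#' Run a full screening evaluation
#'
#' End-to-end orchestration: load (or accept) a score table, apply the
#' requested aggregation protocols per channel, compute per-target metrics
#' with bootstrap intervals, build the benchmark summary table, pairwise
#' method comparisons against the best method, and — when RMSDs and a
#' cognate map are supplied — the cross-docking pose evaluation. All
#' randomness flows from the single config seed; rerunning an identical
#' config reproduces identical outputs.
#'
#' @param scores A `screen_tbl`, or a path to a score CSV/TSV.
#' @param channels Channels to evaluate (default: all channels).
#' @param protocols Subset of `c("best_pose", "worst_pose")`; the score
#'   combinations `cnn_vs` and `affinity_at_best_pose` are added when
#'   `pose_channel` and `affinity_channel` are given.
#' @param pose_channel,affinity_channel Optional channel pair for the score
#'   combinations.
#' @param metrics,alpha,n_boot,level,seed Metric and bootstrap settings
#'   (see [evaluate_screen()]).
#' @param cognates Optional cognate map (tibble `compound`, `receptor`) to
#'   trigger pose evaluation on channels' rankings.
#' @param pose_ranks Ranks for [good_pose_fraction()].
#' @param out_dir Optional directory; when given, writes `metrics.csv`,
#'   `summary.csv`, `comparisons.csv`, optional `pose_eval.csv`, and
#'   `manifest.json`.
#' @return List: `predictions`, `metrics`, `summary`, `comparisons`,
#'   optionally `pose_eval`, and `manifest`.
#' @export
run_evaluation <- function(scores,
                           channels = NULL,
                           protocols = "best_pose",
                           pose_channel = NULL,
                           affinity_channel = NULL,
                           metrics = c("auc", "ef", "nef"),
                           alpha = 0.01, n_boot = 0, level = 0.95, seed = 1,
                           cognates = NULL, pose_ranks = c(1, 3, 5),
                           out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(scores)) scores <- read_score_table(scores)
  channels <- channels %||% screen_channels(scores)$channel
  protocols <- match.arg(protocols, c("best_pose", "worst_pose"),
    several.ok = TRUE)
  preds <- purrr::map_dfr(channels, function(ch) {
    purrr::map_dfr(protocols, function(p) {
      switch(p,
        best_pose = aggregate_best(scores, ch),
        worst_pose = aggregate_worst(scores, ch))
    })
  })
  if (!is.null(pose_channel) && !is.null(affinity_channel)) {
    preds <- dplyr::bind_rows(preds,
      aggregate_product(scores, pose_channel, affinity_channel),
      affinity_at_best_pose(scores, pose_channel, affinity_channel))
  }
  preds$channel <- sub("\\.(best_pose|worst_pose)$", "", preds$method)
  res <- evaluate_screen(preds, metrics = metrics, alpha = alpha,
    n_boot = n_boot, level = level, seed = seed)
  res$channel <- sub("\\.(best_pose|worst_pose)$", "", res$method)
  summ <- summarize_benchmark(res)
  comparisons <- purrr::map_dfr(unique(res$metric), function(m) {
    s <- summ[summ$metric == m, ]
    best_method <- s$method[s$best]
    out <- s[!s$best, c("method", "metric", "p_vs_best")]
    out$best_method <- best_method
    out
  })
  bundle <- list(predictions = preds, metrics = res, summary = summ,
    comparisons = comparisons)
  if (!is.null(cognates) && "rmsd" %in% names(scores)) {
    tasks <- build_crossdock_tasks(scores, cognates)
    bundle$pose_eval <- purrr::map_dfr(channels, function(ch) {
      gp <- good_pose_fraction(tasks, ch, ranks = pose_ranks)
      gp$channel <- ch
      gp$ceiling <- sampling_ceiling(tasks)
      gp
    })
  }
  bundle$manifest <- list(
    package = "screenaudit",
    version = as.character(utils::packageVersion("screenaudit")),
    seed = seed, alpha = alpha, n_boot = n_boot, level = level,
    channels = channels, protocols = protocols, metrics = metrics,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(res, file.path(out_dir, "metrics.csv"))
    readr::write_csv(summ, file.path(out_dir, "summary.csv"))
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    if (!is.null(bundle$pose_eval)) {
      readr::write_csv(bundle$pose_eval, file.path(out_dir, "pose_eval.csv"))
    }
    jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Run a ligand-only bias audit
#'
#' Fits every requested baseline family to the training table, screens the
#' benchmark descriptors with each fitted model, computes per-target
#' metrics, the per-target maxima over configurations, and — when reference
#' method results are supplied — the method-vs-baseline comparison.
#'
#' @param train Training descriptor table (`compound` + features + `pk`).
#' @param descriptors Benchmark descriptor table (`target`, `compound` +
#'   features).
#' @param labels Benchmark labels (`target`, `compound`, `label`); defaults
#'   to label columns carried by `descriptors`.
#' @param families Baseline families to fit (non-empty).
#' @param metrics,alpha,seed,cv_folds Settings.
#' @param reference Optional per-target metric results of an evaluated
#'   method ([evaluate_screen()] output) to compare the baseline against.
#' @param out_dir Optional output directory.
#' @return List: `models` (named list of fits), `metrics` (per target x
#'   family), `best_per_target`, and optionally `comparison` (targets where
#'   the baseline ceiling matches or beats the reference method).
#' @export
run_bias_audit <- function(train, descriptors, labels,
                           families = c("lasso", "random_forest"),
                           metrics = c("auc", "ef", "nef"),
                           alpha = 0.01, seed = 1, cv_folds = 5,
                           reference = NULL, out_dir = NULL) {
  if (length(families) == 0) {
    abort("empty model list", class = "screenaudit_config_error")
  }
  families <- match.arg(families,
    c("lasso", "knn", "decision_tree", "random_forest",
      "gradient_boosting", "svr"), several.ok = TRUE)
  feats <- setdiff(names(train), c("compound", "pk"))
  affinities <- train[, c("compound", "pk")]
  models <- purrr::map(setNames(families, families), function(fam) {
    fit_baseline(train[, c("compound", feats)], affinities,
      baseline_spec(fam, cv_folds = cv_folds, seed = seed))
  })
  desc_feats <- descriptors[, c("compound", feats)]
  preds <- purrr::imap_dfr(models, function(m, fam) {
    screen_with_baseline(m, desc_feats, labels, method = fam)
  })
  res <- evaluate_screen(preds, metrics = metrics, alpha = alpha, seed = seed)
  best <- best_baseline_per_target(res,
    metric = if ("nef" %in% metrics) "nef" else metrics[1])
  bundle <- list(models = models, predictions = preds, metrics = res,
    best_per_target = best)
  if (!is.null(reference)) {
    ref <- reference[reference$metric == best$metric[1], ]
    cmp <- dplyr::inner_join(best,
      dplyr::select(ref, "target", ref_value = "value"), by = "target")
    cmp$baseline_wins <- cmp$value >= cmp$ref_value
    bundle$comparison <- cmp
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(res, file.path(out_dir, "baseline_metrics.csv"))
    readr::write_csv(best, file.path(out_dir, "baseline_best_per_target.csv"))
    if (!is.null(bundle$comparison)) {
      readr::write_csv(bundle$comparison,
        file.path(out_dir, "baseline_comparison.csv"))
    }
  }
  bundle
}
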