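#' Evaluate per-compound predictions on every target
#'
#' Takes a tidy prediction table — one row per (target, compound), as
#' produced by [aggregate_best()] and friends, possibly for several methods
#' stacked with `bind_rows()` — and computes the requested metrics per
#' (target, method), optionally with stratified bootstrap confidence
#' intervals.
#'
#' @param predictions Tibble with columns `target`, `compound`, `label`,
#'   `method`, `value`.
#' @param metrics Subset of `c("auc", "ef", "nef")`.
#' @param alpha Top fraction for EF/NEF.
#' @param n_boot Bootstrap resamples; `0` disables intervals.
#' @param level Interval coverage level.
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with one row per (target, method, metric): `target`,
#'   `method`, `metric`, `alpha` (NA for AUC), `value`, `ci_low`, `ci_high`,
#'   `n_boot`.
#' @export
evaluate_screen <- function(predictions, metrics = c("auc", "ef", "nef"),
                            alpha = 0.01, n_boot = 0, level = 0.95, seed = 1) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(all(c("target", "compound", "label", "method", "value")
    %in% names(predictions)))
  groups <- predictions |>
    dplyr::group_by(.data$target, .data$method) |>
    dplyr::group_split()
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(metrics, function(m) {
      f <- metric_fun(m, alpha)
      row <- tibble(
        target = g$target[1], method = g$method[1], metric = m,
        alpha = if (m == "auc") NA_real_ else alpha,
        value = if (m == "ef") {
          enrichment_factor(g$label, g$value, alpha, ids = g$compound)
        } else if (m == "nef") {
          normalized_ef(g$label, g$value, alpha, ids = g$compound)
        } else {
          f(g$label, g$value)
        },
        ci_low = NA_real_, ci_high = NA_real_, n_boot = NA_integer_
      )
      if (n_boot > 0) {
        bi <- bootstrap_interval(g$label, g$value, metric = m, alpha = alpha,
          n_boot = n_boot, level = level,
          seed = stable_seed(seed, g$target[1], g$method[1], m))
        row$ci_low <- bi$ci_low
        row$ci_high <- bi$ci_high
        row$n_boot <- as.integer(n_boot)
      }
      row
    })
  })
}

# Deterministic 31-bit stream seed derived from a master seed and labels.
stable_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483563
  as.integer(h + 1)
}

#' Summarize a benchmark across targets (median table)
#'
#' Builds the median-over-targets summary for each (method, metric) and
#' flags, per metric column, the best method together with the methods whose
#' per-target distributions are statistically indistinguishable from it
#' (two-sided Mann-Whitney, p > 0.05) — the standard presentation of
#' benchmark league tables (bold = best, italic = tied with best).
#'
#' @param results Per-target metric results from [evaluate_screen()].
#' @param statistic `"median"` or `"mean"`.
#' @param p_threshold Indistinguishability threshold on the Mann-Whitney p.
#' @return Tibble with one row per (method, metric): `method`, `metric`,
#'   `alpha`, `n_targets`, `summary`, `best` (logical), `p_vs_best`,
#'   `tied_with_best` (logical).
#' @export
summarize_benchmark <- function(results, statistic = c("median", "mean"),
                                p_threshold = 0.05) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "median") median else mean
  summ <- results |>
    dplyr::group_by(.data$method, .data$metric, .data$alpha) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      summary = stat_fun(.data$value),
      .groups = "drop"
    )
  purrr::map_dfr(split(summ, summ$metric), function(s) {
    best_method <- s$method[which.max(s$summary)]
    best_values <- results$value[results$method == best_method &
      results$metric == s$metric[1]]
    s$best <- s$method == best_method
    s$p_vs_best <- vapply(s$method, function(m) {
      if (m == best_method) return(NA_real_)
      v <- results$value[results$method == m & results$metric == s$metric[1]]
      compare_distributions(v, best_values)$p_value
    }, numeric(1))
    s$tied_with_best <- !s$best & s$p_vs_best > p_threshold
    s
  })
}

#' Count per-target significant wins between two methods
#'
#' For each target, resamples compounds once per bootstrap iteration
#' (stratified by class) and evaluates both methods on the same resample,
#' giving a bootstrap distribution of the paired metric difference (A - B).
#' A target is a win for A when the percentile interval of that difference
#' lies entirely above zero, a win for B when entirely below, and undecided
#' otherwise. This is the per-target significance reading behind statements
#' like "method X is significantly better on 89 of 117 targets".
#'
#' @param predictions_a,predictions_b Prediction tibbles (see
#'   [evaluate_screen()]) covering the same targets and compounds.
#' @param metric,alpha Metric specification.
#' @param n_boot,level,seed Bootstrap settings.
#' @return List: `wins_a`, `wins_b`, `undecided`, `n_targets`, and
#'   `per_target` (tibble with the interval of the difference per target).
#' @export
significant_win_count <- function(predictions_a, predictions_b,
                                  metric = "nef", alpha = 0.01,
                                  n_boot = 1000, level = 0.95, seed = 1) {
  a <- dplyr::arrange(predictions_a, .data$target, .data$compound)
  b <- dplyr::arrange(predictions_b, .data$target, .data$compound)
  if (!identical(a$target, b$target) || !identical(a$compound, b$compound)) {
    abort("prediction tables must cover the same (target, compound) set",
      class = "screenaudit_integrity_error")
  }
  f <- metric_fun(metric, alpha)
  targets <- unique(a$target)
  per_target <- purrr::map_dfr(targets, function(t) {
    ga <- a[a$target == t, ]
    gb <- b[b$target == t, ]
    y <- label_binary(ga$label)
    idx_act <- which(y == 1L)
    idx_inact <- which(y == 0L)
    diffs <- withr::with_seed(stable_seed(seed, t, metric), {
      vapply(seq_len(n_boot), function(bb) {
        i <- c(sample(idx_act, replace = TRUE), sample(idx_inact, replace = TRUE))
        f(y[i], ga$value[i]) - f(y[i], gb$value[i])
      }, numeric(1))
    })
    qs <- quantile(diffs, c((1 - level) / 2, 1 - (1 - level) / 2),
      type = 7, names = FALSE)
    tibble(target = t,
      diff = f(y, ga$value) - f(y, gb$value),
      ci_low = qs[1], ci_high = qs[2])
  })
  wins_a <- sum(per_target$ci_low > 0)
  wins_b <- sum(per_target$ci_high < 0)
  list(
    wins_a = wins_a, wins_b = wins_b,
    undecided = nrow(per_target) - wins_a - wins_b,
    n_targets = nrow(per_target), per_target = per_target
  )
}
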