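#' Ranking and early-recognition metrics
#'
#' `roc_auc()` is the area under the ROC curve computed by the Mann-Whitney
#' identity with midrank tie handling: the fraction of (active, inactive)
#' pairs where the active outranks the inactive, counting ties as half. A
#' perfect ranking scores 1.0 and a random one 0.5.
#'
#' `enrichment_factor()` is the early-recognition ratio EF(alpha): with
#' `k = ceiling(alpha * N)` compounds in the top fraction and `a` actives
#' among them, EF = (a / k) / (A / N). Its best achievable value
#' ([max_enrichment_factor()]) depends on the active/total counts, so
#' `normalized_ef()` divides EF by that ceiling, giving a value in \[0, 1\]
#' comparable across libraries: 1 means as many actives as possible sit in
#' the top fraction, 0 means none do.
#'
#' Ties at the top-k boundary are resolved deterministically by sorting on
#' (score descending, compound id ascending); no fractional credit is given.
#'
#' @param labels Activity labels: anything [as_screen_table()] accepts
#'   (`"active"`/`"inactive"`, 1/0, TRUE/FALSE).
#' @param scores Numeric scores, higher = predicted more active. `-Inf` is
#'   allowed (compounds ranked last).
#' @param alpha Top fraction in (0, 1]; 0.01 is the conventional "top 1%".
#' @param ids Optional compound identifiers used only for deterministic
#'   tie-breaking at the boundary.
#' @return A single number: AUC in \[0, 1\], EF >= 0, or NEF in \[0, 1\].
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(4, 3, 2, 1)) # 0.75
#' enrichment_factor(rep(c(1, 0), c(10, 990)), 1000:1, alpha = 0.01) # 100
#' @export
roc_auc <- function(labels, scores) {
  y <- label_binary(labels)
  stopifnot(length(y) == length(scores))
  assert_screen_classes(y)
  n_act <- sum(y == 1L)
  n_inact <- sum(y == 0L)
  r <- rank(scores) # midranks
  (sum(r[y == 1L]) - n_act * (n_act + 1) / 2) / (n_act * n_inact)
}

#' @rdname roc_auc
#' @export
enrichment_factor <- function(labels, scores, alpha = 0.01, ids = NULL) {
  y <- label_binary(labels)
  stopifnot(length(y) == length(scores))
  assert_screen_classes(y)
  if (!(alpha > 0 && alpha <= 1)) {
    abort("alpha must lie in (0, 1]", class = "screenaudit_domain_error")
  }
  n <- length(y)
  k <- ceiling(alpha * n)
  ord <- if (is.null(ids)) order(-scores) else order(-scores, as.character(ids))
  a <- sum(y[ord][seq_len(k)])
  (a / k) / (sum(y) / n)
}

#' @rdname roc_auc
#' @param n_actives,n_total Class counts of the library.
#' @export
max_enrichment_factor <- function(n_actives, n_total, alpha = 0.01) {
  if (n_actives <= 0) {
    abort("max EF undefined with zero actives",
      class = "screenaudit_undefined_metric")
  }
  stopifnot(n_actives <= n_total)
  if (!(alpha > 0 && alpha <= 1)) {
    abort("alpha must lie in (0, 1]", class = "screenaudit_domain_error")
  }
  k <- ceiling(alpha * n_total)
  (min(k, n_actives) / k) / (n_actives / n_total)
}

#' @rdname roc_auc
#' @export
normalized_ef <- function(labels, scores, alpha = 0.01, ids = NULL) {
  y <- label_binary(labels)
  enrichment_factor(y, scores, alpha, ids) /
    max_enrichment_factor(sum(y), length(y), alpha)
}

metric_fun <- function(metric, alpha = 0.01) {
  switch(metric,
    auc = function(labels, scores) roc_auc(labels, scores),
    ef = function(labels, scores) enrichment_factor(labels, scores, alpha),
    nef = function(labels, scores) normalized_ef(labels, scores, alpha),
    abort(glue::glue("unknown metric '{metric}'"))
  )
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' The classical large-sample standard error of the trapezoidal AUC given
#' the true AUC and the class counts; used to set recovery tolerances for
#' simulations with a known binormal ground truth.
#'
#' @param auc True (or estimated) AUC.
#' @param n_act,n_inact Number of actives and inactives.
#' @return Standard error of the empirical AUC.
#' @export
hanley_mcneil_se <- function(auc, n_act, n_inact) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_act - 1) * (q1 - auc^2) +
    (n_inact - 1) * (q2 - auc^2)) / (n_act * n_inact))
}

#' Stratified bootstrap confidence interval for a screening metric
#'
#' Percentile interval over `n_boot` resamples in which actives and
#' inactives are resampled separately (preserving class counts, so every
#' resample keeps the metric defined). Reproducible under a fixed seed.
#'
#' @inheritParams roc_auc
#' @param metric `"auc"`, `"ef"` or `"nef"`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Interval coverage level in (0, 1).
#' @param seed Integer seed.
#' @return Named list: `value` (point estimate), `ci_low`, `ci_high`,
#'   `n_boot`.
#' @export
bootstrap_interval <- function(labels, scores, metric = "auc", alpha = 0.01,
                               n_boot = 10000, level = 0.95, seed = 1) {
  if (!(level > 0 && level < 1)) {
    abort("level must lie in (0, 1)", class = "screenaudit_domain_error")
  }
  stopifnot(n_boot >= 100)
  y <- label_binary(labels)
  assert_screen_classes(y)
  f <- metric_fun(metric, alpha)
  idx_act <- which(y == 1L)
  idx_inact <- which(y == 0L)
  stat <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx_act, replace = TRUE), sample(idx_inact, replace = TRUE))
      f(y[i], scores[i])
    }, numeric(1))
  })
  qs <- unname(quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
    type = 7, names = FALSE))
  list(value = f(y, scores), ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Compare two per-target metric distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U rank test on unpaired per-target metric values —
#' the test used to decide whether two scoring methods' per-benchmark metric
#' distributions differ. With both samples of size <= 8 and no ties, the
#' p-value comes from the exact null distribution of the U statistic;
#' otherwise a normal approximation with tie correction is used.
#'
#' @param values_a,values_b Numeric vectors of per-target metric values.
#' @param method_a,method_b Optional method labels for the output.
#' @return One-row tibble: `method_a`, `method_b`, `u`, `p_value`,
#'   `n_a`, `n_b`, `exact`.
#' @examples
#' compare_distributions(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
compare_distributions <- function(values_a, values_b,
                                  method_a = "A", method_b = "B") {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both samples must be non-empty", class = "screenaudit_domain_error")
  }
  stopifnot(all(is.finite(values_a)), all(is.finite(values_b)))
  n1 <- length(values_a)
  n2 <- length(values_b)
  r <- rank(c(values_a, values_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # U for sample a
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- n1 <= 8 && n2 <= 8 && !has_ties
  if (exact) {
    # two-sided: double the smaller tail of the exact U distribution
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    p <- min(p, 1)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0 || u == mu) {
      p <- 1
    } else {
      # continuity-corrected normal approximation
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  tibble(method_a = method_a, method_b = method_b, u = u, p_value = p,
    n_a = n1, n_b = n2, exact = exact)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Midrank handling for ties; the p-value uses the t approximation (the
#' standard large-sample treatment). Errors on constant input, where the
#' correlation is undefined.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return Named list `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    abort("need at least 3 pairs", class = "screenaudit_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
      class = "screenaudit_undefined_correlation")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
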