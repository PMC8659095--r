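#' Specify a ligand-only baseline regression model
#'
#' The bias audit fits simple regression models — Lasso, k-nearest
#' neighbors, decision tree, random forest, gradient-boosted trees, support
#' vector regression — to training-set affinities (pK units) using
#' ligand-only descriptors, then screens a benchmark with the predicted
#' affinity. Good enrichment from such a model signals that the benchmark
#' can be separated by trivial ligand properties rather than modelled
#' protein-ligand interactions.
#'
#' Hyperparameters are chosen on a small fixed grid by k-fold
#' cross-validated squared error; the shipped default grids live in
#' `inst/extdata/baseline_grids.yaml`.
#'
#' @param family One of `"lasso"`, `"knn"`, `"decision_tree"`,
#'   `"random_forest"`, `"gradient_boosting"`, `"svr"`.
#' @param grid Data frame of hyperparameter combinations; `NULL` uses the
#'   shipped default grid for the family.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(family = c("lasso", "knn", "decision_tree",
                                     "random_forest", "gradient_boosting", "svr"),
                          grid = NULL, cv_folds = 5, seed = 1) {
  family <- match.arg(family)
  stopifnot(cv_folds >= 2)
  if (is.null(grid)) grid <- default_baseline_grids()[[family]]
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) {
    abort("hyperparameter grid must be non-empty",
      class = "screenaudit_config_error")
  }
  structure(list(family = family, grid = grid, cv_folds = cv_folds,
    seed = seed), class = "baseline_spec")
}

#' @rdname baseline_spec
#' @export
default_baseline_grids <- function() {
  path <- system.file("extdata", "baseline_grids.yaml", package = "screenaudit")
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(g) expand.grid(g, KEEP.OUT.ATTRS = FALSE))
}

#' Fit a baseline model to affinity training data
#'
#' Grid-searches the spec's hyperparameters by cross-validated mean squared
#' error, then refits the winning configuration on all training data.
#' Features are standardized internally for the scale-sensitive families
#' (lasso, knn, svr). Deterministic under the spec's seed.
#'
#' @param train Tibble with a `compound` column plus numeric feature
#'   columns (e.g. from [compute_descriptors()]), or a numeric matrix with
#'   rownames.
#' @param affinities Tibble with columns `compound`, `pk`, or a named
#'   numeric vector of affinities in pK units.
#' @param spec A [baseline_spec()].
#' @return A `screen_baseline` object supporting `predict()`, [tidy()]
#'   (per-grid-point CV error) and [glance()] (winning configuration).
#' @export
fit_baseline <- function(train, affinities, spec = baseline_spec("lasso")) {
  xy <- align_training(train, affinities)
  x <- xy$x
  y <- xy$y
  if (any(!is.finite(y))) {
    abort("non-finite affinity value(s)", class = "screenaudit_integrity_error")
  }
  if (nrow(x) < spec$cv_folds * 5) {
    abort(glue::glue("need at least {spec$cv_folds * 5} training compounds"),
      class = "screenaudit_config_error")
  }
  scaled <- spec$family %in% c("lasso", "knn", "svr")
  center <- if (scaled) colMeans(x) else rep(0, ncol(x))
  scl <- if (scaled) pmax(apply(x, 2, sd), 1e-12) else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  folds <- withr::with_seed(spec$seed,
    sample(rep(seq_len(spec$cv_folds), length.out = nrow(xs))))
  cv_mse <- vapply(seq_len(nrow(spec$grid)), function(gi) {
    params <- as.list(spec$grid[gi, , drop = FALSE])
    errs <- vapply(seq_len(spec$cv_folds), function(fold) {
      tr <- folds != fold
      fit <- withr::with_seed(stable_seed(spec$seed, spec$family, gi, fold),
        fit_family(spec$family, xs[tr, , drop = FALSE], y[tr], params))
      pred <- predict_family(spec$family, fit, xs[!tr, , drop = FALSE])
      mean((pred - y[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv_mse)
  params <- as.list(spec$grid[best, , drop = FALSE])
  fit <- withr::with_seed(stable_seed(spec$seed, spec$family, best, 0L),
    fit_family(spec$family, xs, y, params))
  structure(list(
    family = spec$family, fit = fit, params = params,
    cv = dplyr::bind_cols(as_tibble(spec$grid), tibble(cv_mse = cv_mse)),
    best_index = best, feature_names = colnames(x),
    center = center, scale = scl, n_train = nrow(x), cv_folds = spec$cv_folds
  ), class = "screen_baseline")
}

align_training <- function(train, affinities) {
  if (is.matrix(train)) {
    train <- dplyr::bind_cols(tibble(compound = rownames(train)), as_tibble(train))
  }
  stopifnot("compound" %in% names(train))
  if (is.numeric(affinities) && !is.null(names(affinities))) {
    affinities <- tibble(compound = names(affinities), pk = unname(affinities))
  }
  stopifnot(all(c("compound", "pk") %in% names(affinities)))
  merged <- dplyr::inner_join(train, affinities, by = "compound")
  # canonical row order: fitting is invariant to the input row order
  merged <- dplyr::arrange(merged, .data$compound)
  feats <- setdiff(names(train), "compound")
  list(x = as.matrix(merged[, feats]), y = merged$pk)
}

fit_family <- function(family, x, y, params) {
  switch(family,
    lasso = glmnet::glmnet(x, y, alpha = 1, lambda = params$lambda),
    knn = caret::knnreg(x, y, k = params$k),
    decision_tree = rpart::rpart(y ~ .,
      data = data.frame(y = y, x, check.names = TRUE),
      cp = params$cp, method = "anova"),
    random_forest = ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      mtry = max(1L, min(ncol(x), round(params$mtry_frac * ncol(x)))),
      seed = sample.int(.Machine$integer.max, 1), num.threads = 1),
    gradient_boosting = xgboost::xgb.train(
      params = list(max_depth = params$max_depth, eta = params$eta,
        objective = "reg:squarederror", nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    svr = e1071::svm(x, y, cost = params$cost, kernel = "radial",
      scale = FALSE),
    abort(glue::glue("unknown family '{family}'"))
  )
}

predict_family <- function(family, fit, x) {
  switch(family,
    lasso = as.numeric(predict(fit, newx = x)),
    knn = as.numeric(predict(fit, x)),
    decision_tree = as.numeric(predict(fit,
      newdata = data.frame(x, check.names = TRUE))),
    random_forest = as.numeric(predict(fit, data = x,
      num.threads = 1)$predictions),
    gradient_boosting = as.numeric(predict(fit,
      xgboost::xgb.DMatrix(x, nthread = 1))),
    svr = as.numeric(predict(fit, x))
  )
}

#' @export
predict.screen_baseline <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    ids <- rownames(newdata)
    x <- newdata
  } else {
    stopifnot("compound" %in% names(newdata))
    ids <- newdata$compound
    feats <- setdiff(names(newdata), "compound")
    x <- as.matrix(newdata[, feats])
  }
  if (!identical(colnames(x), object$feature_names)) {
    if (!setequal(colnames(x), object$feature_names)) {
      abort("feature columns do not match the training features",
        class = "screenaudit_integrity_error")
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  setNames(predict_family(object$family, object$fit, xs), ids)
}

#' @export
print.screen_baseline <- function(x, ...) {
  cat("<screen_baseline>", x$family, "\n")
  cat("  n_train:", x$n_train, " cv_folds:", x$cv_folds, "\n")
  cat("  best params:", paste(names(x$params), unlist(x$params),
    sep = "=", collapse = ", "), "\n")
  cat("  cv mse:", signif(min(x$cv$cv_mse), 4), "\n")
  invisible(x)
}

#' @export
tidy.screen_baseline <- function(x, ...) {
  out <- x$cv
  out$family <- x$family
  out$best <- seq_len(nrow(out)) == x$best_index
  dplyr::relocate(out, "family")
}

#' @export
glance.screen_baseline <- function(x, ...) {
  tibble(family = x$family, n_train = x$n_train, cv_folds = x$cv_folds,
    cv_mse = min(x$cv$cv_mse),
    params = paste(names(x$params), unlist(x$params), sep = "=",
      collapse = ", "))
}

#' Screen a benchmark with a fitted baseline model
#'
#' Predicted affinity is used directly as the ranking score (higher =
#' predicted more active), producing a prediction table compatible with
#' [evaluate_screen()].
#'
#' @param model A fitted [fit_baseline()] model.
#' @param descriptors Benchmark descriptor table (`compound` + features with
#'   the same width as training).
#' @param labels Tibble with columns `target`, `compound`, `label` for the
#'   benchmark compounds.
#' @param method Method label; defaults to the model family.
#' @return Prediction tibble (`target`, `compound`, `label`, `method`,
#'   `value`).
#' @export
screen_with_baseline <- function(model, descriptors, labels, method = NULL) {
  pred <- predict(model, descriptors)
  stopifnot(all(c("target", "compound", "label") %in% names(labels)))
  out <- as_tibble(labels[, c("target", "compound", "label")])
  out$label <- normalize_labels(out$label)
  miss <- setdiff(out$compound, names(pred))
  if (length(miss) > 0) {
    abort(glue::glue(
      "no descriptors for compound(s): {paste(head(miss, 5), collapse = ', ')}"
    ), class = "screenaudit_integrity_error")
  }
  out$method <- method %||% model$family
  out$value <- unname(pred[out$compound])
  out
}

#' Per-target maxima over baseline configurations
#'
#' The bias-audit headline: for each target, the best value of a metric over
#' every (family x descriptor set x training set) baseline configuration —
#' an upper bound on what a ligand-only model can do given the ideal
#' configuration for that target.
#'
#' @param results Per-target metric results ([evaluate_screen()] output,
#'   stacked over configurations; `method` identifies the configuration).
#' @param metric Which metric to maximize (default `"nef"`).
#' @return Tibble with one row per target: `target`, `metric`, `value`
#'   (the maximum), `best_method`.
#' @export
best_baseline_per_target <- function(results, metric = "nef") {
  res <- results[results$metric == metric, ]
  if (nrow(res) == 0) {
    abort(glue::glue("no results for metric '{metric}'"),
      class = "screenaudit_domain_error")
  }
  res |>
    dplyr::group_by(.data$target) |>
    dplyr::slice_max(.data$value, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$target, metric = metric, value = .data$value,
      best_method = .data$method)
}
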