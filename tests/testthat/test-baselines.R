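make_training <- function(n, dim = 5, w = c(2, rep(0, 4)), sigma = 0.05,
                          seed = 1, prefix = "t") {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * dim), n)
    colnames(x) <- paste0("x", seq_len(dim))
    pk <- 6 + drop(x %*% w) + rnorm(n, sd = sigma)
    list(
      features = dplyr::bind_cols(
        tibble::tibble(compound = sprintf("%s%04d", prefix, seq_len(n))),
        tibble::as_tibble(x)),
      pk = tibble::tibble(compound = sprintf("%s%04d", prefix, seq_len(n)),
        pk = pk)
    )
  })
}

test_that("lasso recovers an exact linear signal (held-out R^2 > 0.99)", {
  tr <- make_training(300, sigma = 0.01, seed = 11)
  fit <- fit_baseline(tr$features, tr$pk, baseline_spec("lasso", seed = 2))
  te <- make_training(200, sigma = 0.01, seed = 12, prefix = "h")
  pred <- predict(fit, te$features)
  r2 <- 1 - sum((pred - te$pk$pk)^2) / sum((te$pk$pk - mean(te$pk$pk))^2)
  expect_gt(r2, 0.99)
})

test_that("pure-noise affinities yield near-zero held-out R^2", {
  tr <- make_training(2000, w = rep(0, 5), sigma = 1, seed = 21)
  fit <- fit_baseline(tr$features, tr$pk, baseline_spec("lasso", seed = 2))
  te <- make_training(1000, w = rep(0, 5), sigma = 1, seed = 22, prefix = "h")
  pred <- predict(fit, te$features)
  r2 <- 1 - sum((pred - te$pk$pk)^2) / sum((te$pk$pk - mean(te$pk$pk))^2)
  expect_lt(abs(r2), 0.1)
})

test_that("jointly permuting training rows leaves predictions unchanged", {
  tr <- make_training(120, seed = 31)
  te <- make_training(50, seed = 32, prefix = "h")
  for (fam in c("lasso", "decision_tree", "knn")) {
    f1 <- fit_baseline(tr$features, tr$pk, baseline_spec(fam, seed = 5))
    perm <- withr::with_seed(1, sample(nrow(tr$features)))
    f2 <- fit_baseline(tr$features[perm, ], tr$pk, baseline_spec(fam, seed = 5))
    expect_equal(predict(f1, te$features), predict(f2, te$features),
      tolerance = 1e-8)
  }
})

test_that("every family fits, predicts finitely, and reports its grid", {
  tr <- make_training(80, seed = 41)
  te <- make_training(20, seed = 42, prefix = "h")
  for (fam in names(default_baseline_grids())) {
    fit <- fit_baseline(tr$features, tr$pk, baseline_spec(fam, seed = 3))
    pred <- predict(fit, te$features)
    expect_true(all(is.finite(pred)), info = fam)
    td <- tidy(fit)
    expect_equal(sum(td$best), 1)
    expect_true(all(is.finite(td$cv_mse)))
    gl <- glance(fit)
    expect_equal(gl$family, fam)
    expect_equal(gl$cv_mse, min(td$cv_mse))
  }
})

test_that("fitting is deterministic under a fixed seed", {
  tr <- make_training(100, seed = 51)
  te <- make_training(30, seed = 52, prefix = "h")
  for (fam in c("random_forest", "gradient_boosting")) {
    p1 <- predict(fit_baseline(tr$features, tr$pk,
      baseline_spec(fam, seed = 7)), te$features)
    p2 <- predict(fit_baseline(tr$features, tr$pk,
      baseline_spec(fam, seed = 7)), te$features)
    expect_equal(p1, p2)
  }
})

test_that("screening with a baseline enforces feature compatibility", {
  tr <- make_training(100, seed = 61)
  fit <- fit_baseline(tr$features, tr$pk, baseline_spec("lasso"))
  bench <- make_training(50, seed = 62, prefix = "b")
  labels <- tibble::tibble(target = "T1", compound = bench$features$compound,
    label = rep(c(1, 0), 25))
  out <- screen_with_baseline(fit, bench$features, labels)
  expect_equal(nrow(out), 50)
  expect_equal(out$method, rep("lasso", 50))

  wrong <- bench$features[, 1:3]
  expect_error(screen_with_baseline(fit, wrong, labels),
    class = "screenaudit_integrity_error")
})

test_that("constant benchmark features yield constant predictions", {
  tr <- make_training(100, seed = 71)
  fit <- fit_baseline(tr$features, tr$pk, baseline_spec("lasso"))
  bench <- make_training(20, seed = 72, prefix = "b")$features
  bench[, -1] <- lapply(bench[, -1], function(x) rep(1.5, length(x)))
  pred <- predict(fit, bench)
  expect_equal(length(unique(round(pred, 10))), 1)
})

test_that("errors: non-finite affinity, too-small training set, empty grid", {
  tr <- make_training(100, seed = 81)
  bad_pk <- tr$pk
  bad_pk$pk[3] <- NA
  expect_error(fit_baseline(tr$features, bad_pk, baseline_spec("lasso")),
    class = "screenaudit_integrity_error")
  tiny <- make_training(10, seed = 82)
  expect_error(fit_baseline(tiny$features, tiny$pk, baseline_spec("lasso")),
    class = "screenaudit_config_error")
  expect_error(baseline_spec("lasso", grid = data.frame()),
    class = "screenaudit_config_error")
})

test_that("best_baseline_per_target maximizes per target and is monotone", {
  res <- tibble::tibble(
    target = c("T1", "T1", "T1", "T2"),
    method = c("a", "b", "c", "a"),
    metric = "nef", alpha = 0.01,
    value = c(0.1, 0.4, 0.2, 0.3)
  )
  best <- best_baseline_per_target(res)
  expect_equal(best$value[best$target == "T1"], 0.4)
  expect_equal(best$best_method[best$target == "T1"], "b")
  expect_equal(best$value[best$target == "T2"], 0.3) # single model: itself

  # adding a model never decreases a target's maximum
  more <- dplyr::bind_rows(res, tibble::tibble(target = "T1", method = "d",
    metric = "nef", alpha = 0.01, value = 0.05))
  best2 <- best_baseline_per_target(more)
  expect_true(all(best2$value >= best$value))
})
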