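test_that("best-pose aggregation takes the max over poses and receptors", {
  tbl <- make_screen(scores = list(a = c(0.2, 0.9, 0.4), b = 0.5))
  best <- aggregate_best(tbl, "s")
  expect_equal(best$value[best$compound == "a"], 0.9)
  expect_equal(best$value[best$compound == "b"], 0.5) # single pose: identity

  # two receptors: max over all of them
  df <- dplyr::bind_rows(
    make_pose_df(scores = list(a = c(0.7, 0.2)), labels = c(a = "active"),
      receptor = "r1"),
    make_pose_df(scores = list(a = c(0.8, 0.1)), labels = c(a = "active"),
      receptor = "r2")
  )
  tbl2 <- as_screen_table(df, "s")
  expect_equal(aggregate_best(tbl2, "s")$value, 0.8)
})

test_that("worst-pose aggregation takes the min and never exceeds the best", {
  tbl <- make_screen(scores = list(a = c(0.2, 0.9, 0.4), b = 0.5))
  worst <- aggregate_worst(tbl, "s")
  expect_equal(worst$value[worst$compound == "a"], 0.2)
  expect_equal(worst$value[worst$compound == "b"], 0.5)

  withr::with_seed(42, {
    df <- tibble::tibble(
      target = "T1",
      compound = rep(sprintf("c%02d", 1:20), each = 5),
      label = rep(rep(c("active", "inactive"), 10), each = 5),
      s = rnorm(100)
    )
    tbl <- as_screen_table(df, "s")
    b <- aggregate_best(tbl, "s")
    w <- aggregate_worst(tbl, "s")
    expect_true(all(w$value <= b$value))
  })
})

test_that("strictly increasing transforms select the same argmax pose", {
  withr::with_seed(7, {
    df <- tibble::tibble(
      target = "T1",
      compound = rep(sprintf("c%02d", 1:15), each = 4),
      label = rep(rep(c("active", "inactive", "active"), 5), each = 4),
      s = rnorm(60)
    )
  })
  tbl <- as_screen_table(df, "s")
  b1 <- aggregate_best(tbl, "s")
  df2 <- df
  df2$s <- exp(2 * df2$s + 1)
  tbl2 <- as_screen_table(df2, "s")
  b2 <- aggregate_best(tbl2, "s")
  expect_equal(b2$value, exp(2 * b1$value + 1))
  expect_equal(rank(b1$value), rank(b2$value))
})

test_that("product score multiplies pose probability and clipped affinity", {
  expect_equal(product_score(0.5, 6.0), 3.0)
  expect_equal(product_score(0.0, 9.0), 0.0)
  expect_equal(product_score(1.0, 4.2), 4.2)
  expect_equal(product_score(1.0, -3.0), 0.0) # negative pK clipped
  expect_error(product_score(1.3, 5), class = "screenaudit_domain_error")

  # monotone non-decreasing in each argument on its domain
  withr::with_seed(11, {
    p <- sort(runif(50))
    a <- sort(rnorm(50, 5, 3))
    expect_true(all(diff(product_score(p, 6)) >= 0))
    expect_true(all(diff(product_score(0.4, a)) >= 0))
  })
})

test_that("aggregate_product multiplies per pose, then takes the best pose", {
  df <- tibble::tibble(
    target = "T1", compound = c("a", "a"), label = "active",
    pose = c(0.9, 0.4), aff = c(5.0, 8.0)
  )
  tbl <- as_screen_table(df,
    score_channels(score_channel("pose", kind = "pose_prob"),
      score_channel("aff", kind = "affinity_pK")))
  out <- aggregate_product(tbl, "pose", "aff")
  # per-pose products are 4.5 and 3.2; the max wins
  expect_equal(out$value, 4.5)
  expect_equal(out$method, "cnn_vs")
})

test_that("affinity_at_best_pose picks the top pose's affinity with rank ties", {
  df <- tibble::tibble(
    target = "T1", compound = c("a", "a"), label = "active",
    pose = c(0.9, 0.4), aff = c(5.0, 8.0)
  )
  tbl <- as_screen_table(df,
    score_channels(score_channel("pose", kind = "pose_prob"),
      score_channel("aff", kind = "affinity_pK")))
  expect_equal(affinity_at_best_pose(tbl, "pose", "aff")$value, 5.0)

  # tie in pose score: lower pose_rank wins
  df2 <- tibble::tibble(
    target = "T1", compound = "a", label = "active",
    pose_rank = c(1L, 2L), pose = c(0.6, 0.6), aff = c(4.0, 9.0)
  )
  tbl2 <- as_screen_table(df2,
    score_channels(score_channel("pose", kind = "pose_prob"),
      score_channel("aff", kind = "affinity_pK")))
  expect_equal(affinity_at_best_pose(tbl2, "pose", "aff")$value, 4.0)

  # single pose: its affinity
  tbl3 <- as_screen_table(df2[1, ],
    score_channels(score_channel("pose", kind = "pose_prob"),
      score_channel("aff", kind = "affinity_pK")))
  expect_equal(affinity_at_best_pose(tbl3, "pose", "aff")$value, 4.0)
})

test_that("labelled compounds without poses are ranked last with a warning", {
  tbl <- make_screen(scores = list(a = 0.9, b = 0.1))
  universe <- tibble::tibble(
    target = "T1", compound = c("a", "b", "ghost"),
    label = c("active", "inactive", "inactive")
  )
  expect_warning(
    out <- aggregate_best(tbl, "s", all_compounds = universe),
    "no pose"
  )
  expect_equal(out$value[out$compound == "ghost"], -Inf)
  expect_equal(nrow(out), 3)
})

test_that("unknown channels are rejected", {
  tbl <- make_screen()
  expect_error(aggregate_best(tbl, "nope"), class = "screenaudit_schema_error")
})
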