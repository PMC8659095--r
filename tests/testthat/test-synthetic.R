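test_that("config validation names the offending field", {
  expect_error(synthetic_config(p_good_pose = 1.5), "p_good_pose",
    class = "screenaudit_config_error")
  expect_error(synthetic_config(methods = c(0.5)), "methods",
    class = "screenaudit_config_error")
  expect_error(synthetic_config(flip_rate = c(0.1, 0.2)), "flip_rate",
    class = "screenaudit_config_error")
  expect_error(synthetic_config(train_sigma = 0), "train_sigma",
    class = "screenaudit_config_error")
})

test_that("generation is fully deterministic under a fixed config", {
  cfg <- synthetic_config(n_targets = 2, n_actives = 15, n_inactives = 85,
    n_bits = 64, n_pool = 20, n_train = 50, seed = 33)
  b1 <- generate_benchmark(cfg)
  b2 <- generate_benchmark(cfg)
  expect_identical(as.data.frame(b1$scores), as.data.frame(b2$scores))
  expect_identical(b1$descriptors, b2$descriptors)
  expect_identical(b1$train, b2$train)
  expect_identical(b1$fingerprints, b2$fingerprints)

  p1 <- generate_pose_ensembles(cfg)
  p2 <- generate_pose_ensembles(cfg)
  expect_identical(p1, p2)
})

test_that("binormal separation reproduces the closed-form AUC", {
  # d = 0: AUC ~ 0.5; d = 1.19: AUC ~ 0.8, each within 3 standard errors
  for (d in c(0, 1.19)) {
    cfg <- synthetic_config(n_targets = 1, n_actives = 100,
      n_inactives = 1900, methods = c(m = d), poses_per_compound = 3,
      seed = 50 + round(100 * d))
    b <- generate_benchmark(cfg)
    pred <- aggregate_best(b$scores, "m")
    auc <- roc_auc(pred$label == "active", pred$value)
    auc_true <- pnorm(d / sqrt(2))
    se <- hanley_mcneil_se(auc_true, 100, 1900)
    expect_lt(abs(auc - auc_true), 3 * se)
    expect_equal(b$truth$expected_auc$m, auc_true)
  }
})

test_that("best-pose aggregation recovers the compound-level draw exactly", {
  cfg <- synthetic_config(n_targets = 1, n_actives = 10, n_inactives = 40,
    poses_per_compound = 5, n_receptors = 3, seed = 9)
  b <- generate_benchmark(cfg)
  # pose offsets are non-negative with a zero on (r01, pose 1)
  best_pose <- b$scores[b$scores$receptor == "r01" & b$scores$pose_rank == 1, ]
  agg <- aggregate_best(b$scores, "vina")
  expect_equal(agg$value,
    best_pose$vina[match(agg$compound, best_pose$compound)])
})

test_that("fingerprint similarity responds to the flip rate", {
  cfg0 <- synthetic_config(n_targets = 1, n_actives = 10, n_inactives = 10,
    n_bits = 128, n_pool = 15, flip_rate = 0, seed = 4)
  b0 <- generate_benchmark(cfg0)
  expect_equal(
    avg_max_similarity(b0$fingerprints$actives[[1]], b0$fingerprints$pool), 1)

  cfg5 <- synthetic_config(n_targets = 1, n_actives = 10, n_inactives = 10,
    n_bits = 128, n_pool = 15, flip_rate = 0.5, seed = 4)
  b5 <- generate_benchmark(cfg5)
  expect_lt(
    avg_max_similarity(b5$fingerprints$actives[[1]], b5$fingerprints$pool), 1)
})

test_that("pose ensembles honor coupling and good-pose probability", {
  cfg1 <- synthetic_config(n_targets = 3, n_receptors = 3, p_good_pose = 1,
    score_rmsd_coupling = 1, seed = 14)
  pe1 <- generate_pose_ensembles(cfg1)
  expect_equal(good_pose_fraction(pe1$poses, "score", ranks = 1)$fraction, 1)

  cfg0 <- synthetic_config(n_targets = 3, n_receptors = 3, p_good_pose = 0,
    seed = 15)
  pe0 <- generate_pose_ensembles(cfg0)
  expect_equal(sampling_ceiling(pe0$poses), 0)

  # coupling 0, K = 10: planted rank uniform; rank-1 fraction ~ 0.1
  cfgu <- synthetic_config(n_targets = 40, n_receptors = 5,
    poses_per_compound = 10, p_good_pose = 1, score_rmsd_coupling = 0,
    seed = 16)
  peu <- generate_pose_ensembles(cfgu)
  n_tasks <- nrow(peu$truth)
  frac1 <- good_pose_fraction(peu$poses, "score", ranks = 1)$fraction
  expect_lt(abs(frac1 - 0.1), 3 * sqrt(0.1 * 0.9 / n_tasks))
  # and exactly the planted distribution
  planted_frac <- mean(peu$truth$planted_rank <= 1)
  gp_flat <- mean(tapply(peu$truth$planted_rank <= 1, peu$truth$target, mean))
  expect_equal(frac1, gp_flat)
})

test_that("benchmark files round-trip through the writers", {
  cfg <- synthetic_config(n_targets = 2, n_actives = 8, n_inactives = 32,
    n_bits = 64, n_pool = 10, n_train = 40, seed = 77)
  b <- generate_benchmark(cfg)
  dir <- tempfile("bench")
  write_benchmark(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scores.csv", "descriptors.csv", "train.csv", "fingerprint_pool.csv",
      "fingerprint_actives.csv", "truth.json")))))
  back <- read_score_table(file.path(dir, "scores.csv"))
  expect_equal(back$vina, b$scores$vina, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$expected_auc$vina, b$truth$expected_auc$vina)

  # hex fingerprint encoding is lossless
  fp <- b$fingerprints$pool
  expect_equal(unname(hex_to_fp(fp_to_hex(fp))), unname(fp))
  expect_equal(rownames(hex_to_fp(fp_to_hex(fp))), rownames(fp))
})
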