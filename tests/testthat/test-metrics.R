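test_that("roc_auc matches pair counting, with midrank ties", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(4, 3, 2, 1)), 0.75)
  expect_equal(roc_auc(rep(c(1, 0), c(3, 5)), c(9, 8, 7, 1:5)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4)), 0.5) # all tied
  expect_error(roc_auc(c(1, 1), c(1, 2)),
    class = "screenaudit_undefined_metric")
})

test_that("roc_auc agrees with brute force and an independent library", {
  withr::with_seed(101, {
    for (i in 1:50) {
      n <- sample(4:20, 1)
      y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      s <- round(rnorm(n), sample(c(0, 1, 8), 1)) # rounding induces ties
      expect_equal(roc_auc(y, s), brute_auc(y, s))
    }
    y <- c(rep(1, 30), rep(0, 170))
    s <- rnorm(200) + 0.8 * y
    expect_equal(
      roc_auc(y, s),
      as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    )
  })
})

test_that("auc symmetry and rank invariance hold", {
  withr::with_seed(5, {
    y <- sample(0:1, 50, replace = TRUE)
    y[1:2] <- 0:1
    s <- round(rnorm(50), 1)
    expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)
    expect_equal(roc_auc(y, s), roc_auc(y, qnorm(pnorm(s)) * 3 + 2))
  })
})

test_that("enrichment factor counts actives in the top fraction", {
  # N=1000, A=10, 5 actives among the top 10 by score
  y <- rep(0, 1000)
  y[c(1, 3, 5, 7, 9, 500:504)] <- 1
  s <- 1000:1
  expect_equal(enrichment_factor(y, s, 0.01), (5 / 10) / (10 / 1000)) # 50
  expect_equal(normalized_ef(y, s, 0.01), 0.5)

  # no actives in the top k
  y2 <- rep(c(0, 1), c(990, 10))
  expect_equal(enrichment_factor(y2, 1000:1, 0.01), 0)
  expect_equal(normalized_ef(y2, 1000:1, 0.01), 0)

  # alpha = 1 is identically 1
  withr::with_seed(2, {
    y3 <- sample(0:1, 40, replace = TRUE)
    y3[1:2] <- 0:1
    expect_equal(enrichment_factor(y3, rnorm(40), 1), 1)
  })
})

test_that("max enrichment factor follows the closed form", {
  expect_equal(max_enrichment_factor(10, 1000, 0.01), 100)
  expect_equal(max_enrichment_factor(50, 1000, 0.01), 20)
  expect_equal(max_enrichment_factor(30, 30, 0.01), 1)
  expect_error(max_enrichment_factor(0, 10), class = "screenaudit_undefined_metric")
})

test_that("EF is bounded by its maximum and monotone in promoted actives", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(50:200, 1)
      a <- sample(2:10, 1)
      y <- sample(rep(c(1, 0), c(a, n - a)))
      s <- rnorm(n)
      ef <- enrichment_factor(y, s, 0.05)
      expect_gte(ef, 0)
      expect_lte(ef, max_enrichment_factor(a, n, 0.05))
      expect_true(normalized_ef(y, s, 0.05) >= 0 &&
        normalized_ef(y, s, 0.05) <= 1)
    }
  })
  # promoting one active across the boundary never decreases EF
  y <- rep(c(1, 0), c(5, 95))
  s <- seq(100, 1)
  names <- sprintf("c%03d", 1:100)
  base_y <- rep(0, 100)
  base_y[c(1, 50, 60, 70, 80)] <- 1
  ef0 <- enrichment_factor(base_y, s, 0.05, ids = names)
  promoted <- base_y
  promoted[c(50, 2)] <- c(0, 1) # move an active above the k-boundary
  expect_gte(enrichment_factor(promoted, s, 0.05, ids = names), ef0)
})

test_that("stratified bootstrap brackets the point estimate and is seeded", {
  y <- rep(c(1, 0), c(20, 80))
  s <- rnorm(100) + y
  b1 <- bootstrap_interval(y, s, "auc", n_boot = 500, seed = 3)
  b2 <- bootstrap_interval(y, s, "auc", n_boot = 500, seed = 3)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$value)
  expect_gte(b1$ci_high, b1$value)

  # degenerate separation: zero-width interval at the metric value
  yd <- rep(c(1, 0), c(5, 20))
  sd_ <- rep(c(1, 0), c(5, 20))
  bd <- bootstrap_interval(yd, sd_, "auc", n_boot = 200, seed = 1)
  expect_equal(bd$ci_low, 1)
  expect_equal(bd$ci_high, 1)
  expect_error(bootstrap_interval(y, s, "auc", level = 1.2),
    class = "screenaudit_domain_error")
})

test_that("Mann-Whitney comparison is exact for small untied samples", {
  out <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p_value, 0.1)
  expect_true(out$exact)

  expect_equal(compare_distributions(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # ties: midranks, p still a probability
  p_tie <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 3))$p_value
  expect_true(p_tie >= 0 && p_tie <= 1)

  expect_error(compare_distributions(numeric(0), 1),
    class = "screenaudit_domain_error")
})

test_that("exact Mann-Whitney agrees with wilcox.test and its approximation", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      a <- rnorm(n1)
      b <- rnorm(n2, 0.5)
      mine <- compare_distributions(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
    # n = 8 vs 8 without ties: approximation within 0.02 of exact
    for (i in 1:20) {
      a <- rnorm(8)
      b <- rnorm(8, 0.3)
      exact_p <- compare_distributions(a, b)$p_value
      r <- rank(c(a, b))
      u <- sum(r[1:8]) - 8 * 9 / 2
      z <- (u - 32 - sign(u - 32) * 0.5) / sqrt(8 * 8 * 17 / 12)
      approx_p <- min(1, 2 * pnorm(-abs(z)))
      expect_lt(abs(exact_p - approx_p), 0.02)
    }
  })
})

test_that("spearman correlation recovers monotone and anti-monotone pairings", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_error(spearman_correlation(rep(1, 5), 1:5),
    class = "screenaudit_undefined_correlation")
  expect_error(spearman_correlation(1:2, 2:1),
    class = "screenaudit_domain_error")
})
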