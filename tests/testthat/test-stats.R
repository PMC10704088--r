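# Descriptive summaries and nonparametric comparisons.

test_that("summaries use the linear-interpolation quantile convention", {
  s <- cohort_summary(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$p25, 1.5)
  expect_equal(s$p75, 2.5)
  s2 <- cohort_summary(rep(7, 10))
  expect_equal(unlist(s2), c(median = 7, p25 = 7, p75 = 7))
  # permutation invariance and column-wise operation
  set.seed(2)
  x <- rnorm(101)
  expect_equal(cohort_summary(x), cohort_summary(sample(x)))
  df <- data.frame(a = x, b = 2 * x)
  sm <- cohort_summary(df)
  expect_equal(sm["b", "median"], 2 * sm["a", "median"])
})

test_that("the Mann-Whitney test agrees with exhaustive enumeration", {
  # small worked dataset, no ties
  x <- c(1.1, 2.3, 2.9, 4.1, 5.6, 7.2)
  y <- c(2.0, 3.8, 4.4, 6.0, 6.8, 8.5)
  gt <- group_tests(c(x, y), rep(c("a", "b"), each = 6))
  or <- mw_exhaustive(x, y)
  expect_equal(gt$method, "mann-whitney")
  expect_equal(unname(gt$statistic), or$u)
  expect_lt(abs(gt$p_value - or$p), 0.08)
  # fully separated groups reach the minimal U of zero
  gt2 <- group_tests(c(1:6, 11:16), rep(c("a", "b"), each = 6))
  u <- unname(gt2$statistic)
  expect_equal(min(u, 36 - u), 0)
  expect_true(gt2$significant)
})

test_that("permuted labels on identical data are not significant", {
  set.seed(14)
  x <- rnorm(40)
  g <- sample(rep(c("a", "b"), each = 20))
  expect_false(group_tests(x, g)$significant)
  g3 <- sample(rep(c("a", "b", "c"), length.out = 40))
  expect_false(group_tests(x, g3)$significant)
})

test_that("the Kruskal-Wallis test agrees with exhaustive enumeration", {
  x <- c(3.1, 5.2, 1.4, 6.3, 7.7, 2.2, 4.4, 8.9, 5.9, 0.7, 9.4, 3.8)
  g <- rep(c("u", "v", "w"), each = 4)
  gt <- group_tests(x, g)
  or <- kw_exhaustive(x, g)
  expect_equal(gt$method, "kruskal-wallis")
  expect_equal(unname(gt$statistic), or$h, tolerance = 1e-12)
  expect_lt(abs(gt$p_value - or$p), 0.05)
  expect_true(is.data.frame(gt$posthoc))
  expect_equal(nrow(gt$posthoc), 3)
})

test_that("Dunn's z statistics follow the rank-sum formula", {
  set.seed(3)
  x <- c(rnorm(8), rnorm(8, 3), rnorm(8, 6))
  g <- rep(c("a", "b", "c"), each = 8)
  ph <- dunn_posthoc(x, g)
  # hand computation for the a-b pair (no ties)
  r <- rank(x)
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt(24 * 25 / 12 * (1 / 8 + 1 / 8))
  expect_equal(ph$z[ph$group1 == "a" & ph$group2 == "b"], z_ab,
               tolerance = 1e-12)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_raw * 3))
  expect_true(all(ph$p_adjusted <= 1))
  # strongly separated extreme groups are detected
  expect_true(ph$significant[ph$group1 == "a" & ph$group2 == "c"])
  expect_error(group_tests(1:5, c("a", "a", "b", "b", "c")),
               "2 observations")
})

test_that("trend regression recovers exact and noisy slopes", {
  x <- seq(50, 65, length.out = 40)
  tr <- suppressWarnings(trend_regression(x, 3 - 0.009 * x))  # exact fit
  expect_equal(tr$slope, -0.009, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-10)
  # independent response: flat slope, non-significant at a fixed seed
  set.seed(20)
  y <- rnorm(1000)
  x2 <- runif(1000, 50, 65)
  tr2 <- trend_regression(x2, y)
  expect_gt(tr2$p_value, 0.05)
  # duplicating the data keeps the slope and sharpens the p-value
  set.seed(21)
  yy <- 1 + 0.02 * x + rnorm(40, sd = 0.5)
  t1 <- trend_regression(x, yy)
  t2 <- trend_regression(c(x, x), c(yy, yy))
  expect_equal(t2$slope, t1$slope, tolerance = 1e-12)
  expect_lt(t2$p_value, t1$p_value)
})
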