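test_that("identical samples give a null two-group comparison", {
  d <- data.frame(v = rep(c(1.3, 2.7, 3.1, 4.9), 2),
                  g = rep(c("a", "b"), each = 4))
  res <- two_group_compare(d, v, g, method = "t")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_equal(res$mean1, res$mean2)
})

test_that("Mann-Whitney matches the exact enumeration oracle", {
  d <- data.frame(v = 1:6, g = rep(c("a", "b"), each = 3))
  res <- two_group_compare(d, v, g, method = "mann_whitney")
  expect_equal(res$statistic, 0) # complete separation: U = 0
  expect_equal(res$p_value, oracle_mann_whitney(1:3, 4:6)) # = 2/20
  expect_equal(res$p_value, 0.1)

  set.seed(9)
  for (rep in 1:10) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    x <- round(runif(m, 0, 100), 3) # continuous draws: no ties
    y <- round(runif(n, 0, 100), 3)
    d <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(m, n)))
    res <- two_group_compare(d, v, g, method = "mann_whitney")
    expect_equal(res$p_value, oracle_mann_whitney(x, y),
                 info = sprintf("rep %d (m=%d, n=%d)", rep, m, n))
  }
})

test_that("the auto rule picks Mann-Whitney for skewed groups and logs why", {
  set.seed(2)
  d <- data.frame(v = c(rexp(40)^3, rnorm(40, 2)),
                  g = rep(c("a", "b"), each = 40))
  res <- two_group_compare(d, v, g, method = "auto")
  expect_equal(res$test, "mann_whitney")
  expect_match(res$method_reason, "normality screen failed")

  d2 <- data.frame(v = c(rnorm(40), rnorm(40, 0.5)),
                   g = rep(c("a", "b"), each = 40))
  res2 <- two_group_compare(d2, v, g, method = "auto")
  expect_equal(res2$test, "welch_t")
})

test_that("group size preconditions are enforced", {
  expect_error(
    two_group_compare(data.frame(v = 1:3, g = c("a", "a", "b")), v, g),
    "at least 2"
  )
})

test_that("proportion comparison reproduces the Yates closed form", {
  same <- proportion_compare(10, 50, 10, 50)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- proportion_compare(10, 100, 30, 100)
  ora <- oracle_yates_chisq(10, 90, 30, 70)
  expect_equal(res$statistic, ora$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, ora$p_value, tolerance = 1e-12)

  # frail vs non-frail female proportions, cohort-sized counts
  fem <- proportion_compare(34, 44, 153, 207)
  ora2 <- oracle_yates_chisq(34, 10, 153, 54)
  expect_equal(fem$p_value, ora2$p_value, tolerance = 1e-12)
  expect_equal(100 * fem$prop1, 77.3, tolerance = 0.05)
  expect_equal(100 * fem$prop2, 73.9, tolerance = 0.05)
  expect_gt(fem$p_value, 0.05)
  expect_error(proportion_compare(5, 4, 1, 10), "0 <= k <= n")
})

test_that("Wilson interval matches its closed form and stays in [0, 1]", {
  ci <- wilson_ci(8, 10)
  z <- qnorm(0.975)
  p <- 0.8; n <- 10
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  expect_equal(unname(ci["lower"] + ci["upper"]), 2 * centre, tolerance = 1e-12)
  expect_true(all(ci >= 0 & ci <= 1))
  ci0 <- wilson_ci(0, 20)
  expect_equal(unname(ci0["lower"]), 0)
})

test_that("correlations hit the monotone extremes and the rank oracle", {
  d <- data.frame(x = c(3, 1, 4, 1.5, 9), y = c(6, 2, 8, 3, 18))
  expect_equal(correlate(d, x, y, "spearman")$estimate, 1)
  d$y2 <- -d$y
  expect_equal(correlate(d, x, y2, "spearman")$estimate, -1)

  set.seed(13)
  dt <- data.frame(x = sample(1:8, 20, replace = TRUE),
                   y = sample(1:8, 20, replace = TRUE))
  got <- correlate(dt, x, y, "spearman")
  # oracle: Pearson on midranks, p from the same t transform via cor.test
  rx <- rank(dt$x); ry <- rank(dt$y)
  expect_equal(got$estimate, cor(rx, ry), tolerance = 1e-12)
  ct <- cor.test(rx, ry, method = "pearson")
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)

  expect_error(correlate(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "degenerate")
  expect_error(correlate(data.frame(x = 1:2, y = 2:1), x, y), "at least 3")
})

test_that("linear fits recover exact lines and the r^2 identity", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  # an exact line triggers R's "essentially perfect fit" note, which is fine
  fit <- suppressWarnings(linear_fit(d, x, y))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  set.seed(3)
  d2 <- data.frame(x = rnorm(40), y = rnorm(40))
  fit2 <- linear_fit(d2, x, y)
  expect_equal(fit2$r^2, correlate(d2, x, y, "pearson")$estimate^2,
               tolerance = 1e-12)
  expect_equal(glance(fit2)$r_squared, summary(fit2$lm)$r.squared,
               tolerance = 1e-12)
  td <- tidy(fit2)
  expect_equal(td$estimate[2], fit2$slope)
  expect_error(linear_fit(data.frame(x = rep(1, 5), y = 1:5), x, y), "var\\(x\\)")
})

test_that("index-vs-FTS-5 regression is positive and powered on default cohorts", {
  hits <- 0
  for (s in 1:20) {
    co <- score_cohort(simulate_study(seed = 100 + s)$cohort)
    fit <- linear_fit(co, index, fts5_total)
    if (fit$slope > 0 && fit$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 16) # >= 80% of seeds
})
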