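fts_row <- function(v) {
  stats::setNames(as.data.frame(as.list(v)), unname(fts5_domains()))
}

test_that("FTS-5 total and the frailty threshold are strict", {
  expect_equal(fts5_score(fts_row(rep(0, 5)))$fts5_total, 0)
  expect_false(fts5_score(fts_row(rep(0, 5)))$frail)

  at25 <- fts5_score(fts_row(c(5, 5, 5, 5, 5)))
  above <- fts5_score(fts_row(c(5, 5, 5, 5, 6)))
  expect_equal(at25$fts5_total, 25)
  expect_false(at25$frail) # exactly 25 is not frail
  expect_equal(above$fts5_total, 26)
  expect_true(above$frail)

  top <- fts5_score(fts_row(rep(10, 5)))
  expect_equal(top$fts5_total, 50)
  expect_true(top$frail)
})

test_that("FTS-5 rejects out-of-range domains by name", {
  bad <- fts_row(c(5, 11, 5, 5, 5))
  expect_error(fts5_score(bad), "physical_activity")
  expect_error(fts5_score(fts_row(c(-1, 5, 5, 5, 5))), "nutrition")
  expect_error(fts5_score(fts_row(rep(5, 5))[, -3]), "missing")
})

test_that("FTS-5 classification is monotone in every domain", {
  base <- c(5, 5, 5, 5, 5)
  for (k in 1:5) {
    lo <- base; lo[k] <- 4
    hi <- base; hi[k] <- 6
    expect_false(fts5_score(fts_row(lo))$frail)
    expect_true(fts5_score(fts_row(hi))$frail)
  }
  # permutation invariance of the total
  set.seed(1)
  v <- runif(5, 0, 10)
  expect_equal(fts5_score(fts_row(v))$fts5_total,
               fts5_score(fts_row(sample(v)))$fts5_total)
})

test_that("FTS subscales sum the named domains and validate names", {
  d <- fts_row(c(1, 2, 3, 7, 5))
  expect_equal(fts_subscale(d, subset = names(fts5_domains()))$fts3,
               fts5_score(d)$fts5_total)
  expect_equal(fts_subscale(d, subset = "strength")$fts3, 7)
  expect_equal(fts_subscale(d)$fts3, 2 + 7 + 5) # default FTS-3 triple
  expect_error(fts_subscale(d, subset = character()), "non-empty")
  expect_error(fts_subscale(d, subset = c("strength", "strength")), "duplicate")
  expect_error(fts_subscale(d, subset = "grip"), "unknown")
})

test_that("FTS-3 tracks FTS-5 closely on the default synthetic cohort", {
  co <- score_cohort(simulate_study(seed = 2)$cohort)
  res <- correlate(co, fts3, fts5_total, method = "spearman")
  expect_gt(res$estimate, 0.8)
})

test_that("CONUT subscores, totals and categories follow the bands", {
  healthy <- conut_score(data.frame(albumin = 4.2, lymphocytes = 2000,
                                    cholesterol = 200))
  expect_equal(healthy$albumin_sub, 0L)
  expect_equal(healthy$lymphocyte_sub, 0L)
  expect_equal(healthy$cholesterol_sub, 0L)
  expect_equal(healthy$conut_total, 0L)
  expect_equal(as.character(healthy$conut_category), "normal")

  worst <- conut_score(data.frame(albumin = 2.4, lymphocytes = 700,
                                  cholesterol = 90))
  expect_equal(unlist(worst[c("albumin_sub", "lymphocyte_sub", "cholesterol_sub")],
                      use.names = FALSE), c(6L, 3L, 3L))
  expect_equal(worst$conut_total, 12L)
  expect_equal(as.character(worst$conut_category), "severe")

  expect_equal(as.character(conut_category(c(8, 9))), c("moderate", "severe"))
  expect_equal(as.character(conut_category(c(0, 1, 2, 4, 5))),
               c("normal", "normal", "light", "light", "moderate"))
  expect_error(conut_score(data.frame(albumin = 4, lymphocytes = 2000)),
               "cholesterol")
})

test_that("CONUT banding is exhaustive, non-overlapping and monotone", {
  # independent lookup written as literal threshold chains
  oracle_sub <- list(
    albumin = function(v) if (v >= 3.5) 0L else if (v >= 3.0) 2L else if (v >= 2.5) 4L else 6L,
    lymphocytes = function(v) if (v >= 1600) 0L else if (v >= 1200) 1L else if (v >= 800) 2L else 3L,
    cholesterol = function(v) if (v >= 180) 0L else if (v >= 140) 1L else if (v >= 100) 2L else 3L
  )
  bands <- conut_bands()
  for (nm in names(bands)) {
    b <- bands[[nm]]
    vals <- sort(c(seq(0, 2.5 * b$edges[1], length.out = 400),
                   b$edges, b$edges - 1e-9, b$edges + 1e-9))
    got <- urbanfrailty:::conut_subscore(vals, b)
    expect_equal(got, vapply(vals, oracle_sub[[nm]], integer(1)))
    # every value maps to exactly one subscore, non-increasing in the analyte
    expect_true(all(diff(got) <= 0))
    expect_false(anyNA(got))
  }
})

test_that("CONUT category is non-decreasing in the total", {
  cats <- conut_category(0:12)
  expect_true(all(diff(as.integer(cats)) >= 0))
})
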