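test_that("Spearman-to-Pearson conversion hits the fixed points", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1)
  expect_equal(spearman_to_pearson(-1), -1)
  expect_error(spearman_to_pearson(1.2), "\\[-1, 1\\]")
})

test_that("the copula conversion reproduces target Spearman in simulation", {
  set.seed(99)
  n <- 1e5
  for (target in c(0.33, -0.4)) {
    rho_p <- spearman_to_pearson(target)
    z <- rnorm(n)
    w <- rho_p * z + sqrt(1 - rho_p^2) * rnorm(n)
    expect_equal(cor(rank(z), rank(w)), target, tolerance = 0.01)
  }
})

test_that("logistic intercept calibration solves the prevalence equation", {
  expect_equal(calibrate_logistic_intercept(0.175, 0, rnorm(10)),
               qlogis(0.175))
  set.seed(4)
  z <- rnorm(500)
  a <- calibrate_logistic_intercept(0.175, 0.4, z)
  expect_equal(mean(plogis(a + 0.4 * z)), 0.175, tolerance = 1e-6)
  zs <- c(z, -z) # exactly symmetric sample
  expect_equal(calibrate_logistic_intercept(0.5, 0.7, zs), 0, tolerance = 1e-6)
  expect_error(calibrate_logistic_intercept(1.5, 0, z), "strictly in")
})

test_that("city generation is deterministic and Poisson in intensity", {
  cfg <- small_city_config()
  a <- generate_city(cfg, seed = 5)
  b <- generate_city(cfg, seed = 5)
  expect_identical(a$layers, b$layers)
  expect_identical(a$clusters, b$clusters)
  # every cell belongs to exactly one of the 6 clusters
  expect_true(all(a$clusters %in% 1:6))
  expect_equal(sort(unique(as.vector(a$clusters))), 1:6)

  # doubling one intensity doubles the mean count (3 SE tolerance)
  base_int <- default_facility_intensity()
  dbl_int <- base_int
  dbl_int["pharmacies"] <- 2 * base_int["pharmacies"]
  counts <- sapply(1:100, function(s) {
    c1 <- generate_city(city_config(grid = cfg$grid, intensity = base_int,
                                    cluster_centers = default_cluster_centers()[, c("x", "y")] / 2.5,
                                    cluster_sd = 400), seed = s)
    c2 <- generate_city(city_config(grid = cfg$grid, intensity = dbl_int,
                                    cluster_centers = default_cluster_centers()[, c("x", "y")] / 2.5,
                                    cluster_sd = 400), seed = 1000 + s)
    c(nrow(c1$layers$pharmacies$points), nrow(c2$layers$pharmacies$points))
  })
  m1 <- mean(counts[1, ]); m2 <- mean(counts[2, ])
  se <- sqrt(var(counts[2, ]) / 100 + 4 * var(counts[1, ]) / 100)
  expect_lt(abs(m2 - 2 * m1), 3 * se + 1e-9)
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- small_study(seed = 8)
  b <- small_study(seed = 8)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a$cohort, f1)
  write_cohort_csv(b$cohort, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c_other <- small_study(seed = 9)
  expect_false(identical(a$cohort$x, c_other$cohort$x))
})

test_that("every generated participant satisfies frail <=> total > 25", {
  for (s in c(1, 2)) {
    st <- small_study(seed = s, n = 120)
    drawn <- st$cohort$frail
    sc <- fts5_score(st$cohort) # recomputes `frail` from the domain scores
    expect_identical(sc$frail, drawn)
    expect_true(all(sc$fts5_total >= 0 & sc$fts5_total <= 50))
    expect_true(all(vapply(unname(fts5_domains()), function(cl) {
      all(sc[[cl]] >= 0 & sc[[cl]] <= 10)
    }, logical(1))))
  }
})

test_that("null configuration yields null dependence", {
  null_panel <- default_lab_panel()
  null_panel$rho_index <- 0
  null_cfg <- cohort_config(frailty_index_slope = 0, lab_panel = null_panel,
                            handgrip_slope = 0, fts_index_slope = 0,
                            n_lab_subset = 251)
  nrep <- 50
  rhos <- vapply(seq_len(nrep), function(s) {
    st <- simulate_study(seed = 200 + s, cohort_config = null_cfg)
    correlate(st$cohort, index, bilirubin, "spearman")$estimate
  }, numeric(1))
  # under the null the Spearman sd at n = 251 is 1/sqrt(250) ~ 0.063, so
  # |rho| < 0.1 holds in ~89% of cohorts; assert >= 80% to leave binomial
  # room at 50 replicates, plus no systematic drift
  expect_gte(mean(abs(rhos) < 0.1), 0.8)
  expect_lt(abs(mean(rhos)), 0.03)
})

test_that("lab analytes respect their marginal supports", {
  st <- small_study(seed = 21, n = 100)
  lab <- st$cohort[st$cohort$in_lab_subset, ]
  panel <- default_lab_panel()
  for (j in seq_len(nrow(panel))) {
    v <- lab[[panel$analyte[j]]]
    expect_true(all(v >= panel$lower[j] & v <= panel$upper[j]),
                info = panel$analyte[j])
  }
  # analytes are missing outside the lab subset
  expect_true(all(is.na(st$cohort$bilirubin[!st$cohort$in_lab_subset])))
})

test_that("handgrip calibration solves the quartile moment equations", {
  cal <- calibrate_handgrip_slope(n_seeds = 5, seed = 3)
  # the returned coefficients reproduce the targets at the estimated z-means
  expect_equal(cal$base + cal$slope * cal$z_q1, 22.8, tolerance = 1e-10)
  expect_equal(cal$base + cal$slope * cal$z_q4, 19.1, tolerance = 1e-10)
  expect_lt(cal$slope, 0)
})
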