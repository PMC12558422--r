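scored_small_cohort <- function(seed = 6, n = 100) {
  st <- small_study(seed = seed, n = n)
  co <- dplyr::bind_cols(
    st$cohort,
    participant_distances(st$cohort[, c("x", "y")], st$city$layers)
  )
  score_cohort(co)
}

test_that("report assembly requires its input columns by name", {
  co <- scored_small_cohort()
  expect_error(build_report(dplyr::select(co, -bmi)), "bmi")
  expect_error(build_report(dplyr::select(co, -quartile, -index)),
               "index.*quartile|quartile.*index")
})

test_that("the report covers every table and figure panel", {
  co <- scored_small_cohort()
  rep <- build_report(co)
  expect_s3_class(rep, "uf_report")
  expect_setequal(
    rep$table2$variable,
    c("female", "age", "bmi", paste0("cluster_", sort(unique(co$cluster))))
  )
  expect_equal(nrow(rep$table3$cells), 4 * 5) # 4 quartiles x 5 variables
  expect_setequal(rep$table3$tests$variable,
                  c("frail_pct", "fts5", "handgrip", "gait_speed", "bmi"))
  # the correlation panel lists exactly the analytes present in the input
  expect_setequal(rep$table4$analyte,
                  intersect(default_lab_panel()$analyte, names(co)))
  expect_equal(nrow(rep$fig3), 7)
  expect_true(all(rep$fig3$facility_type %in% facility_types()))
  ps <- tidy(rep)$p_value
  expect_true(all(ps[!is.na(ps)] >= 0 & ps[!is.na(ps)] <= 1))
})

test_that("a cohort with no frail participants still yields a valid report", {
  co <- scored_small_cohort()
  # force everyone non-frail by zeroing the domain scores and rescoring
  for (cl in unname(fts5_domains())) co[[cl]] <- 0
  co <- score_cohort(dplyr::select(co, -fts5_total, -frail, -fts3))
  rep <- build_report(co)
  expect_true(all(rep$table2$test == "not_computable"))
  expect_true(all(is.na(rep$table2$p_value)))
  expect_true(all(rep$fig3$test == "not_computable"))
  expect_s3_class(rep$table4, "tbl_df") # correlations unaffected
})

test_that("reports are order-invariant", {
  co <- scored_small_cohort()
  rep1 <- build_report(co)
  set.seed(1)
  rep2 <- build_report(co[sample(nrow(co)), ])
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report_json(rep1, f1)
  write_report_json(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("report summaries agree with direct recomputation", {
  co <- scored_small_cohort()
  rep <- build_report(co)
  fem <- rep$table2[rep$table2$variable == "female", ]
  expect_equal(fem$nonfrail, 100 * mean(co$sex[!co$frail] == "female"))
  q4 <- co[co$quartile == "Q4", ]
  cell <- rep$table3$cells
  expect_equal(
    cell$estimate[cell$quartile == "Q4" & cell$variable == "handgrip"],
    mean(q4$handgrip_kg)
  )
  lab <- co[co$in_lab_subset, ]
  bili <- rep$table4[rep$table4$analyte == "bilirubin", ]
  expect_equal(bili$rho, correlate(lab, index, bilirubin, "spearman")$estimate)
})
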