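#' Append clinical scores to a cohort
#'
#' Runs the FTS-5 total and frailty classification, the FTS-3 subscale and the
#' CONUT score over a cohort table in one call.
#'
#' @param cohort A cohort tibble with the FTS domain columns and (for CONUT)
#'   `albumin`, `lymphocytes`, `cholesterol`.
#' @param frailty_threshold Frailty cut-off on the FTS-5 total (default 25).
#' @param fts3_subset Domain subset of the FTS-3 (default
#'   [fts3_default_subset()]).
#' @param bands CONUT banding (default [conut_bands()]).
#' @return The cohort with `fts5_total`, `frail`, `fts3` and the CONUT
#'   columns appended.
#' @export
score_cohort <- function(cohort, frailty_threshold = 25,
                         fts3_subset = fts3_default_subset(),
                         bands = conut_bands()) {
  cohort <- fts5_score(cohort, threshold = frailty_threshold)
  cohort <- fts_subscale(cohort, subset = fts3_subset)
  if (all(c("albumin", "lymphocytes", "cholesterol") %in% names(cohort))) {
    cohort <- conut_score(cohort, bands = bands)
  }
  cohort
}

# Two-group contrast that degrades gracefully: groups too small for the test
# yield a "not_computable" row instead of an error.
safe_two_group <- function(data, value, by, method = "auto") {
  res <- tryCatch(
    two_group_compare(data, {{ value }}, {{ by }}, method = method),
    error = function(e) NULL
  )
  if (!is.null(res)) return(res)
  tibble::tibble(
    variable = rlang::as_name(rlang::enquo(value)), test = "not_computable",
    method_reason = "group too small or degenerate",
    group1 = NA_character_, group2 = NA_character_,
    n1 = NA_integer_, n2 = NA_integer_,
    mean1 = NA_real_, sd1 = NA_real_, mean2 = NA_real_, sd2 = NA_real_,
    median1 = NA_real_, median2 = NA_real_,
    statistic = NA_real_, p_value = NA_real_
  )
}

safe_proportion <- function(k1, n1, k2, n2) {
  res <- tryCatch(proportion_compare(k1, n1, k2, n2), error = function(e) NULL)
  if (!is.null(res)) return(res)
  tibble::tibble(
    test = "not_computable",
    k1 = k1, n1 = n1, prop1 = ifelse(n1 > 0, k1 / n1, NA_real_),
    lower1 = NA_real_, upper1 = NA_real_,
    k2 = k2, n2 = n2, prop2 = ifelse(n2 > 0, k2 / n2, NA_real_),
    lower2 = NA_real_, upper2 = NA_real_,
    statistic = NA_real_, p_value = NA_real_
  )
}

report_required_cols <- function() {
  c("participant_id", "sex", "age", "bmi", "cluster", "index", "quartile",
    "fts5_total", "frail", "fts3", "handgrip_kg", "gait_speed_ms")
}

#' Assemble the full analysis report
#'
#' Builds the study's statistical surface from a scored cohort:
#'
#' * `table2` — demographics (female %, age, BMI) and the six spatial-cluster
#'   proportions, frail vs non-frail, each with its test;
#' * `table3` — frailty prevalence, FTS-5, handgrip, gait speed and BMI by
#'   urban-quality quartile, with an across-quartile test and the Q4-vs-Q1
#'   contrast per variable;
#' * `table4` — Spearman correlation of the summary index with every analyte
#'   present, on the laboratory subset;
#' * `fig3` — mean distance to each facility type by frailty status;
#' * `fig4` — linear fits of FTS-5 and FTS-3 on the index, and the index by
#'   frailty status;
#' * `fig6` — CONUT by frailty status and the CONUT-vs-index fit.
#'
#' The report is deterministic and order-invariant: rows are sorted by
#' `participant_id` before any computation. Group contrasts that cannot be
#' computed (e.g. an empty frail group) are emitted as `not_computable` rows
#' rather than errors.
#'
#' @param cohort A scored cohort (see [score_cohort()]) carrying the columns
#'   named by `report_required_cols()`; `dist_<facility_type>` columns, if
#'   present, feed the facility-distance panel, and analyte columns feed the
#'   correlation panel (rows outside the lab subset may be NA).
#' @return A list of class `uf_report` with elements `table2`, `table3`,
#'   `table4`, `fig3`, `fig4`, `fig6`, `meta`.
#' @export
build_report <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing <- setdiff(report_required_cols(), names(cohort))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cohort <- dplyr::arrange(cohort, .data$participant_id)
  cohort$frail_status <- factor(ifelse(cohort$frail, "frail", "nonfrail"),
                                levels = c("nonfrail", "frail"))
  nf <- cohort[!cohort$frail, ]
  fr <- cohort[cohort$frail, ]

  # --- Table 2: demographics and cluster proportions by frailty status -----
  prop_row <- function(variable, k_nf, k_fr) {
    res <- safe_proportion(k_nf, nrow(nf), k_fr, nrow(fr))
    tibble::tibble(
      variable = variable, type = "proportion",
      nonfrail = 100 * res$prop1, nonfrail_lower = 100 * res$lower1,
      nonfrail_upper = 100 * res$upper1,
      frail = 100 * res$prop2, frail_lower = 100 * res$lower2,
      frail_upper = 100 * res$upper2,
      nonfrail_sd = NA_real_, frail_sd = NA_real_,
      n_nonfrail = nrow(nf), n_frail = nrow(fr),
      test = res$test, p_value = res$p_value
    )
  }
  mean_row <- function(variable, col) {
    res <- safe_two_group(cohort, !!rlang::sym(col), frail_status)
    tibble::tibble(
      variable = variable, type = "mean",
      nonfrail = res$mean1, nonfrail_lower = NA_real_, nonfrail_upper = NA_real_,
      frail = res$mean2, frail_lower = NA_real_, frail_upper = NA_real_,
      nonfrail_sd = res$sd1, frail_sd = res$sd2,
      n_nonfrail = nrow(nf), n_frail = nrow(fr),
      test = res$test, p_value = res$p_value
    )
  }
  table2 <- dplyr::bind_rows(
    prop_row("female", sum(nf$sex == "female"), sum(fr$sex == "female")),
    mean_row("age", "age"),
    mean_row("bmi", "bmi"),
    purrr::map_dfr(sort(unique(cohort$cluster)), function(k) {
      prop_row(paste0("cluster_", k), sum(nf$cluster == k), sum(fr$cluster == k))
    })
  )

  # --- Table 3: frailty metrics by index quartile --------------------------
  cohort$quartile <- factor(cohort$quartile, levels = c("Q1", "Q2", "Q3", "Q4"))
  cont_vars <- c(fts5 = "fts5_total", handgrip = "handgrip_kg",
                 gait_speed = "gait_speed_ms", bmi = "bmi")
  cells <- purrr::map_dfr(levels(cohort$quartile), function(q) {
    sub <- cohort[cohort$quartile == q, ]
    k <- sum(sub$frail)
    ci <- if (nrow(sub) > 0) wilson_ci(k, nrow(sub)) else c(lower = NA, upper = NA)
    dplyr::bind_rows(
      tibble::tibble(
        quartile = q, variable = "frail_pct",
        estimate = 100 * k / max(nrow(sub), 1), sd = NA_real_,
        lower = 100 * ci[["lower"]], upper = 100 * ci[["upper"]], n = nrow(sub)
      ),
      purrr::map_dfr(names(cont_vars), function(v) {
        tibble::tibble(
          quartile = q, variable = v,
          estimate = mean(sub[[cont_vars[[v]]]]),
          sd = stats::sd(sub[[cont_vars[[v]]]]),
          lower = NA_real_, upper = NA_real_, n = nrow(sub)
        )
      })
    )
  })
  q14 <- cohort[cohort$quartile %in% c("Q1", "Q4"), ]
  q14$quartile <- droplevels(q14$quartile)
  tests <- dplyr::bind_rows(
    {
      tab <- table(cohort$quartile, cohort$frail_status)
      overall <- tryCatch(
        suppressWarnings(stats::chisq.test(tab))$p.value,
        error = function(e) NA_real_
      )
      con <- safe_proportion(
        sum(q14$frail[q14$quartile == "Q4"]), sum(q14$quartile == "Q4"),
        sum(q14$frail[q14$quartile == "Q1"]), sum(q14$quartile == "Q1")
      )
      tibble::tibble(variable = "frail_pct", overall_test = "chisq",
                     overall_p = overall, q4_vs_q1_test = con$test,
                     q4_vs_q1_p = con$p_value)
    },
    purrr::map_dfr(names(cont_vars), function(v) {
      col <- cont_vars[[v]]
      overall <- tryCatch(
        summary(stats::aov(stats::reformulate("quartile", col),
                           data = cohort))[[1]][["Pr(>F)"]][1],
        error = function(e) NA_real_
      )
      con <- safe_two_group(q14, !!rlang::sym(col), quartile)
      tibble::tibble(variable = v, overall_test = "anova", overall_p = overall,
                     q4_vs_q1_test = con$test, q4_vs_q1_p = con$p_value)
    })
  )
  table3 <- list(cells = cells, tests = tests)

  # --- Table 4: index vs analytes (lab subset) -----------------------------
  lab <- if ("in_lab_subset" %in% names(cohort)) {
    cohort[cohort$in_lab_subset, ]
  } else {
    cohort
  }
  analytes <- intersect(default_lab_panel()$analyte, names(cohort))
  table4 <- purrr::map_dfr(analytes, function(a) {
    res <- tryCatch(
      correlate(lab, index, !!rlang::sym(a), method = "spearman"),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(analyte = a, rho = NA_real_, p_value = NA_real_,
                     n = sum(is.finite(lab[[a]])))
    } else {
      tibble::tibble(analyte = a, rho = res$estimate, p_value = res$p_value,
                     n = res$n)
    }
  })

  # --- Fig 3: facility distances by frailty status -------------------------
  dist_cols <- grep("^dist_", names(cohort), value = TRUE)
  fig3 <- purrr::map_dfr(dist_cols, function(col) {
    res <- safe_two_group(cohort, !!rlang::sym(col), frail_status)
    tibble::tibble(
      facility_type = sub("^dist_", "", col),
      mean_nonfrail = res$mean1,
      sem_nonfrail = res$sd1 / sqrt(res$n1),
      mean_frail = res$mean2,
      sem_frail = res$sd2 / sqrt(res$n2),
      test = res$test, p_value = res$p_value
    )
  })

  # --- Fig 4: frailty scores vs index --------------------------------------
  fig4 <- list(
    fts5_fit = glance(linear_fit(cohort, index, fts5_total)),
    fts3_fit = glance(linear_fit(cohort, index, fts3)),
    index_by_status = safe_two_group(cohort, index, frail_status)
  )

  # --- Fig 6: CONUT by status and vs index ---------------------------------
  fig6 <- if ("conut_total" %in% names(cohort)) {
    lab_scored <- lab[is.finite(lab$conut_total), ]
    list(
      conut_by_status = safe_two_group(lab_scored, conut_total, frail_status),
      conut_fit = tryCatch(glance(linear_fit(lab_scored, index, conut_total)),
                           error = function(e) NULL),
      conut_index_spearman = tryCatch(
        correlate(lab_scored, index, conut_total, method = "spearman"),
        error = function(e) NULL
      )
    )
  } else {
    NULL
  }

  structure(
    list(
      table2 = table2, table3 = table3, table4 = table4,
      fig3 = fig3, fig4 = fig4, fig6 = fig6,
      meta = list(
        n = nrow(cohort), n_frail = nrow(fr),
        n_lab = nrow(lab), analytes = analytes
      )
    ),
    class = "uf_report"
  )
}

#' @export
print.uf_report <- function(x, ...) {
  cat(sprintf(
    "<uf_report> n = %d (%d frail, %.1f%%); %d analytes in correlation panel\n",
    x$meta$n, x$meta$n_frail, 100 * x$meta$n_frail / x$meta$n,
    length(x$meta$analytes)
  ))
  f <- x$fig4$fts5_fit
  cat(sprintf("  FTS-5 ~ index: slope %.3f, r = %.3f, p = %.4g\n",
              f$slope, f$r, f$p_value))
  sig <- x$table4[!is.na(x$table4$p_value) & x$table4$p_value < 0.05, ]
  if (nrow(sig)) {
    cat("  index-correlated analytes (p < 0.05): ",
        paste(sprintf("%s (rho %.2f)", sig$analyte, sig$rho), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Collect every p-value in a report
#'
#' @param x A `uf_report`.
#' @param ... Unused.
#' @return A tibble with `panel`, `item`, `p_value`.
#' @method tidy uf_report
#' @export
tidy.uf_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(panel = "table2", item = x$table2$variable,
                   p_value = x$table2$p_value),
    tibble::tibble(panel = "table3_overall", item = x$table3$tests$variable,
                   p_value = x$table3$tests$overall_p),
    tibble::tibble(panel = "table3_q4_vs_q1", item = x$table3$tests$variable,
                   p_value = x$table3$tests$q4_vs_q1_p),
    tibble::tibble(panel = "table4", item = x$table4$analyte,
                   p_value = x$table4$p_value),
    if (nrow(x$fig3)) tibble::tibble(panel = "fig3", item = x$fig3$facility_type,
                                     p_value = x$fig3$p_value),
    tibble::tibble(
      panel = "fig4",
      item = c("fts5_fit", "fts3_fit", "index_by_status"),
      p_value = c(x$fig4$fts5_fit$p_value, x$fig4$fts3_fit$p_value,
                  x$fig4$index_by_status$p_value)
    ),
    if (!is.null(x$fig6)) tibble::tibble(
      panel = "fig6",
      item = c("conut_by_status", "conut_index_spearman"),
      p_value = c(x$fig6$conut_by_status$p_value,
                  x$fig6$conut_index_spearman$p_value %||% NA_real_)
    )
  )
}
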