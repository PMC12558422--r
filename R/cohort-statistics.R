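#' Compare a continuous variable between two groups
#'
#' Two-sided comparison of a continuous variable between two groups, as used
#' for frail vs non-frail and Q4 vs Q1 contrasts. `method = "t"` runs Welch's
#' t test; `method = "mann_whitney"` the Mann-Whitney U test (exact when both
#' groups are small and untied, otherwise the normal approximation with tie
#' correction); `method = "auto"` screens each group for normality (Shapiro at
#' `alpha_normality`) and picks Mann-Whitney when either group fails, Welch's
#' t otherwise. The choice and its reason are recorded in the result.
#'
#' @param data A data frame.
#' @param value Column with the continuous variable (tidy-eval).
#' @param by Column defining the two groups (tidy-eval); must have exactly two
#'   non-missing levels.
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @param alpha_normality Significance level of the Shapiro normality screen
#'   used by `"auto"` (default 0.05).
#' @return A one-row tibble: `variable`, `test`, `method_reason`, `group1`,
#'   `group2`, `n1`, `n2`, `mean1`, `sd1`, `mean2`, `sd2`, `median1`,
#'   `median2`, `statistic`, `p_value`.
#' @examples
#' two_group_compare(
#'   data.frame(g = rep(c("a", "b"), each = 10), v = c(rnorm(10), rnorm(10, 1))),
#'   v, g, method = "t"
#' )
#' @export
two_group_compare <- function(data, value, by, method = c("auto", "t", "mann_whitney"),
                              alpha_normality = 0.05) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(by), data)
  var_name <- rlang::as_name(rlang::enquo(value))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- as.factor(droplevels(factor(g[keep])))
  if (nlevels(g) != 2) {
    stop("grouping column must have exactly two levels", call. = FALSE)
  }
  x <- v[g == levels(g)[1]]
  y <- v[g == levels(g)[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }

  reason <- method
  if (method == "auto") {
    normal_enough <- function(z) {
      if (length(z) < 3 || stats::sd(z) == 0) return(FALSE)
      stats::shapiro.test(z)$p.value >= alpha_normality
    }
    if (normal_enough(x) && normal_enough(y)) {
      method <- "t"
      reason <- "auto: both groups pass normality screen"
    } else {
      method <- "mann_whitney"
      reason <- "auto: normality screen failed in at least one group"
    }
  }

  if (method == "t") {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    test <- "welch_t"
  } else {
    # exact null distribution when feasible (small untied samples), otherwise
    # the tie-corrected normal approximation with continuity correction
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) < 50 && length(y) < 50
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    test <- "mann_whitney"
  }

  tibble::tibble(
    variable = var_name, test = test, method_reason = reason,
    group1 = levels(g)[1], group2 = levels(g)[2],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), sd1 = stats::sd(x),
    mean2 = mean(y), sd2 = stats::sd(y),
    median1 = stats::median(x), median2 = stats::median(y),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Compare two proportions
#'
#' 2x2 chi-square test with Yates continuity correction, reporting each
#' proportion with its 95% Wilson score interval.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param conf_method Confidence interval method; `"wilson"` (default) or
#'   `"wald"`.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A one-row tibble: `test`, `k1`, `n1`, `prop1`, `lower1`, `upper1`,
#'   `k2`, `n2`, `prop2`, `lower2`, `upper2`, `statistic`, `p_value`.
#' @examples
#' proportion_compare(34, 44, 153, 207)
#' @export
proportion_compare <- function(k1, n1, k2, n2,
                               conf_method = c("wilson", "wald"),
                               conf_level = 0.95) {
  conf_method <- match.arg(conf_method)
  for (pair in list(c(k1, n1), c(k2, n2))) {
    if (pair[2] <= 0 || pair[1] < 0 || pair[1] > pair[2]) {
      stop("need 0 <= k <= n with n > 0 in both groups", call. = FALSE)
    }
  }
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  ci <- function(k, n) {
    if (conf_method == "wilson") {
      wilson_ci(k, n, conf_level)
    } else {
      p <- k / n
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      c(lower = max(0, p - z * sqrt(p * (1 - p) / n)),
        upper = min(1, p + z * sqrt(p * (1 - p) / n)))
    }
  }
  ci1 <- ci(k1, n1)
  ci2 <- ci(k2, n2)
  tibble::tibble(
    test = "chisq_yates",
    k1 = k1, n1 = n1, prop1 = k1 / n1, lower1 = ci1[["lower"]], upper1 = ci1[["upper"]],
    k2 = k2, n2 = n2, prop2 = k2 / n2, lower2 = ci2[["lower"]], upper2 = ci2[["upper"]],
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Correlation between two variables
#'
#' Spearman (default) or Pearson correlation with a two-sided p-value from
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))`. The Spearman
#' coefficient is computed as the Pearson correlation of the average-rank
#' transforms, so ties are handled by midranks.
#'
#' @param data A data frame.
#' @param x,y Columns to correlate (tidy-eval).
#' @param method `"spearman"` or `"pearson"`.
#' @return A one-row tibble: `x`, `y`, `method`, `estimate`, `statistic` (the
#'   t value), `p_value`, `n`.
#' @examples
#' correlate(data.frame(a = 1:10, b = (1:10)^2), a, b)
#' @export
correlate <- function(data, x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) stop("correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  if (method == "spearman") {
    xv <- rank(xv, ties.method = "average")
    yv <- rank(yv, ties.method = "average")
  }
  r <- stats::cor(xv, yv)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    x = rlang::as_name(rlang::enquo(x)), y = rlang::as_name(rlang::enquo(y)),
    method = method, estimate = r, statistic = tstat, p_value = p, n = n
  )
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression as used for the index-vs-score panels, returning
#' a fitted object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @param data A data frame.
#' @param x,y Predictor and response columns (tidy-eval).
#' @return An object of class `uf_fit` wrapping the [stats::lm()] fit, with
#'   `slope`, `intercept`, `r` (Pearson), `p_value` (two-sided, slope = 0) and
#'   `n` readily accessible.
#' @examples
#' fit <- linear_fit(data.frame(x = 1:10, y = 2 * (1:10) + 1), x, y)
#' glance(fit)
#' @export
linear_fit <- function(data, x, y) {
  data <- tibble::as_tibble(data)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  d <- tibble::tibble(x = xv[keep], y = yv[keep])
  if (nrow(d) < 3) stop("linear fit needs at least 3 complete pairs", call. = FALSE)
  if (stats::var(d$x) == 0) stop("degenerate input: var(x) = 0", call. = FALSE)
  fit <- stats::lm(y ~ x, data = d)
  coefs <- summary(fit)$coefficients
  r <- if (stats::var(d$y) == 0) NA_real_ else stats::cor(d$x, d$y)
  structure(
    list(
      lm = fit, data = d,
      x_name = rlang::as_name(rlang::enquo(x)),
      y_name = rlang::as_name(rlang::enquo(y)),
      slope = unname(coefs["x", "Estimate"]),
      intercept = unname(coefs["(Intercept)", "Estimate"]),
      r = r,
      p_value = unname(coefs["x", "Pr(>|t|)"]),
      n = nrow(d)
    ),
    class = "uf_fit"
  )
}

#' @export
print.uf_fit <- function(x, ...) {
  cat(sprintf(
    "<uf_fit> %s ~ %s: slope %.4g, intercept %.4g, r = %.3f, p = %.4g (n = %d)\n",
    x$y_name, x$x_name, x$slope, x$intercept, x$r, x$p_value, x$n
  ))
  invisible(x)
}

#' Tidy a linear fit
#'
#' @param x A `uf_fit` object from [linear_fit()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`).
#' @importFrom generics tidy
#' @method tidy uf_fit
#' @export
tidy.uf_fit <- function(x, ...) {
  coefs <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$x_name),
    estimate = unname(coefs[, "Estimate"]),
    std_error = unname(coefs[, "Std. Error"]),
    statistic = unname(coefs[, "t value"]),
    p_value = unname(coefs[, "Pr(>|t|)"])
  )
}

#' One-row summary of a linear fit
#'
#' @param x A `uf_fit` object from [linear_fit()].
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r`, `r_squared`,
#'   `p_value`, `n`.
#' @importFrom generics glance
#' @method glance uf_fit
#' @export
glance.uf_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r = x$r, r_squared = x$r^2,
    p_value = x$p_value, n = x$n
  )
}
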