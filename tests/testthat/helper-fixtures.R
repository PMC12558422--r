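# Shared fixtures: everything is generated in code at test time.

# Brute-force nearest-neighbour oracle, written independently of the package's
# running-minimum implementation: full distance matrix, then per-row minimum.
oracle_nearest <- function(qx, qy, px, py) {
  apply(
    outer(qx, px, "-")^2 + outer(qy, py, "-")^2,
    1,
    function(row2) sqrt(min(row2))
  )
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of the
# pooled observations to the two groups.
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Yates-corrected chi-square for a 2x2 table from the textbook closed form.
oracle_yates_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (max(abs(a * d - b * c) - n / 2, 0))^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- num / den
  list(statistic = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# A small deterministic city for fast pipeline tests.
small_city_config <- function() {
  city_config(
    grid = grid_spec(n_rows = 40, n_cols = 40, cell_size = 50),
    cluster_centers = tibble::tibble(
      cluster = 1:6,
      x = c(1500, 1400, 900, 1000, 800, 500),
      y = c(1500, 500, 1600, 1000, 400, 800)
    ),
    cluster_sd = 400
  )
}

small_study <- function(seed = 1, n = 80) {
  simulate_study(seed,
                 city_config = small_city_config(),
                 cohort_config = cohort_config(n_participants = n,
                                               n_lab_subset = min(30, n)))
}
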