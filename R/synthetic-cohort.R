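#' Convert a target Spearman correlation to a Gaussian-copula correlation
#'
#' For a bivariate normal copula, the Pearson correlation `rho_p` of the
#' latent normals and the Spearman correlation `rho_s` of the generated pair
#' are linked by `rho_s = (6 / pi) * asin(rho_p / 2)`. Inverting gives
#' `rho_p = 2 * sin(pi * rho_s / 6)`, which is the latent correlation used to
#' induce a desired Spearman correlation between the urban-quality index and
#' each laboratory analyte.
#'
#' @param rho_s Target Spearman correlation(s), in `[-1, 1]`.
#' @return Latent Pearson correlation(s).
#' @examples
#' spearman_to_pearson(c(0, 0.33, 1))
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) > 1)) {
    stop("Spearman correlations must lie in [-1, 1]", call. = FALSE)
  }
  2 * sin(pi * rho_s / 6)
}

#' Calibrate the logistic intercept for a target prevalence
#'
#' Given standardized index values `z` and a fixed slope `beta`, finds the
#' intercept `alpha` such that the cohort-average frailty probability
#' `mean(plogis(alpha + beta * z))` equals the target prevalence. The mean is
#' strictly increasing in `alpha`, so the root is found by monotone
#' root-finding to a tolerance of 1e-6 on the prevalence scale (closed form
#' `alpha = qlogis(target)` when `beta = 0`).
#'
#' @param target_prev Target marginal prevalence, strictly in (0, 1).
#' @param beta Logistic slope per index standard deviation.
#' @param z Numeric vector of standardized index values.
#' @return The intercept `alpha`.
#' @export
calibrate_logistic_intercept <- function(target_prev, beta, z) {
  if (!is.finite(target_prev) || target_prev <= 0 || target_prev >= 1) {
    stop("target prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(z))) stop("z values must be finite", call. = FALSE)
  if (beta == 0) return(stats::qlogis(target_prev))
  f <- function(alpha) mean(stats::plogis(alpha + beta * z)) - target_prev
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("no finite bracket for alpha", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Default laboratory marginal distributions and index correlations
#'
#' One row per analyte of the biochemical/haematological panel: the marginal
#' (a truncated normal with `mean`, `sd`, support `[lower, upper]`) and the
#' target Spearman correlation `rho_index` between the analyte and the
#' urban-quality summary index. Marginal locations and spreads are typical
#' clinical values for community-dwelling older adults. The lymphocyte
#' channel's `rho_index` is not a reported quantity: it is the calibration
#' knob through which the CONUT-vs-index correlation (target 0.25) is induced,
#' since the CONUT total reacts to the index only through its three analytes.
#'
#' @return A tibble with columns `analyte`, `mean`, `sd`, `lower`, `upper`,
#'   `rho_index`.
#' @export
default_lab_panel <- function() {
  tibble::tribble(
    ~analyte,           ~mean, ~sd,   ~lower, ~upper, ~rho_index,
    "got",                 24,    8,       1,    Inf,      -0.08,
    "alk_phos",            85,   25,       5,    Inf,      -0.09,
    "ldh",                180,   40,      20,    Inf,       0.01,
    "bilirubin",          0.7,  0.3,    0.05,    Inf,       0.33,
    "glycemia",           105,   25,      40,    Inf,       0.19,
    "uric_acid",          5.5,  1.4,     0.5,    Inf,       0.09,
    "cholesterol",        190,   38,      60,    Inf,      -0.13,
    "bun",                 18,    6,       2,    Inf,      -0.19,
    "calcium",            9.4,  0.5,       6,    Inf,       0.03,
    "phosphorus",         3.5,  0.5,       1,    Inf,      -0.10,
    "total_proteins",     7.0,  0.5,       4,    Inf,      -0.11,
    "albumin",            4.1, 0.35,       1,    Inf,       0.10,
    "crp",                0.4,  0.4,       0,    Inf,      -0.08,
    "esr",                 18,   10,       1,    Inf,      -0.20,
    "serum_iron",          85,   30,       5,    Inf,       0.27,
    "tibc",               320,   50,     100,    Inf,      -0.02,
    "transferrin_sat",     27,    9,       1,    100,       0.24,
    "hemoglobin",        13.8,  1.4,       5,    Inf,       0.19,
    "hematocrit",        41.5,    4,      15,    Inf,       0.21,
    "rbc",                4.6,  0.5,       2,    Inf,       0.26,
    "mchc",              33.5,    1,      25,    Inf,      -0.07,
    "mcv",                 90,    5,      60,    Inf,      -0.11,
    "rdw",               13.5,  1.2,      10,    Inf,       0.23,
    "wbc",               6800, 1800,    1000,    Inf,      -0.06,
    "platelets",       250000, 60000,  20000,    Inf,       0.07,
    "mpv",                9.5,    1,       5,    Inf,       0.07,
    "lymphocytes",       1900,  600,     100,    Inf,      -0.40
  )
}

#' Configuration of the synthetic cohort
#'
#' Defaults encode the study conditions the generator is calibrated to:
#' 251 participants with a marginal frailty prevalence of 17.5%, frail/
#' non-frail BMI of 31.5 (4.4) / 28.5 (4.5) kg/m2, handgrip strength whose
#' bottom/top urban-quality-quartile means sit near 22.8 / 19.1 kg, and
#' laboratory analytes whose Spearman correlation with the summary index
#' matches the targets in [default_lab_panel()] (bilirubin 0.33, serum iron
#' 0.27, transferrin saturation 0.24, RBC 0.26, RDW 0.23), with the CONUT
#' score correlating about 0.25 with the index.
#'
#' @param n_participants Cohort size (default 251).
#' @param n_lab_subset Size of the laboratory subsample (default 70).
#' @param target_frailty_prevalence Marginal frailty prevalence (default
#'   0.175).
#' @param frailty_index_slope Logistic slope of frailty on the standardized
#'   index (logit per index SD, default 0.25; positive, so frailty is more
#'   frequent where urban quality is higher).
#' @param bmi_frail,bmi_nonfrail Length-2 vectors `c(mean, sd)` of BMI by
#'   frailty group.
#' @param handgrip_base,handgrip_slope,handgrip_sd Handgrip model
#'   `base + slope * z + Normal(0, sd)` in kg; base and slope are calibrated
#'   by moment matching so that the Q1/Q4 quartile means hit 22.8/19.1 kg
#'   (see [calibrate_handgrip_slope()]).
#' @param gait_base,gait_slope,gait_sd Gait-speed model (m/s), analogous.
#' @param age_frail,age_nonfrail Length-2 `c(mean, sd)` of age by group.
#' @param p_female_nonfrail,p_female_frail Probability of female sex by group.
#' @param fts_nonfrail,fts_frail Length-2 `c(mean, sd)` of the latent FTS-5
#'   total by group, truncated to [0, 25] / (25, 50] respectively.
#' @param fts_index_slope Shift of the latent FTS-5 mean per index SD.
#' @param fts_split_shape Dirichlet concentration used to split a total into
#'   the five domain scores.
#' @param lab_panel Analyte table as in [default_lab_panel()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 251,
                          n_lab_subset = 70,
                          target_frailty_prevalence = 0.175,
                          frailty_index_slope = 0.25,
                          bmi_frail = c(31.5, 4.4),
                          bmi_nonfrail = c(28.5, 4.5),
                          handgrip_base = 21.22,
                          handgrip_slope = -1.44,
                          handgrip_sd = 6.5,
                          gait_base = 0.95,
                          gait_slope = -0.02,
                          gait_sd = 0.2,
                          age_frail = c(75.6, 7.4),
                          age_nonfrail = c(73.8, 5.2),
                          p_female_nonfrail = 0.739,
                          p_female_frail = 0.772,
                          fts_nonfrail = c(11, 6),
                          fts_frail = c(28.5, 3.5),
                          fts_index_slope = 1.5,
                          fts_split_shape = 4,
                          lab_panel = default_lab_panel()) {
  if (n_participants < 8) stop("n_participants must be at least 8", call. = FALSE)
  if (n_lab_subset < 3 || n_lab_subset > n_participants) {
    stop("n_lab_subset must lie in [3, n_participants]", call. = FALSE)
  }
  if (target_frailty_prevalence <= 0 || target_frailty_prevalence >= 1) {
    stop("target_frailty_prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  lab_panel <- tibble::as_tibble(lab_panel)
  if (any(abs(lab_panel$rho_index) >= 1)) {
    stop("analyte |rho_index| must be < 1", call. = FALSE)
  }
  if (any(lab_panel$sd <= 0) || bmi_frail[2] <= 0 || bmi_nonfrail[2] <= 0) {
    stop("all standard deviations must be > 0", call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_lab_subset = as.integer(n_lab_subset),
      target_frailty_prevalence = target_frailty_prevalence,
      frailty_index_slope = frailty_index_slope,
      bmi_frail = bmi_frail, bmi_nonfrail = bmi_nonfrail,
      handgrip_base = handgrip_base, handgrip_slope = handgrip_slope,
      handgrip_sd = handgrip_sd,
      gait_base = gait_base, gait_slope = gait_slope, gait_sd = gait_sd,
      age_frail = age_frail, age_nonfrail = age_nonfrail,
      p_female_nonfrail = p_female_nonfrail, p_female_frail = p_female_frail,
      fts_nonfrail = fts_nonfrail, fts_frail = fts_frail,
      fts_index_slope = fts_index_slope, fts_split_shape = fts_split_shape,
      lab_panel = lab_panel
    ),
    class = "cohort_config"
  )
}

# Deterministic sub-seed so the cohort draws do not replay the city's RNG
# stream when both are driven by the same user seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}

# Split totals into 5 domain scores in [0, 10] summing to the total:
# Dirichlet proportions with bounded rejection; an equal split (always
# feasible for totals <= 50) if no draw satisfies the bound.
split_fts_domains <- function(total, shape, max_tries = 200) {
  n <- length(total)
  out <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      w <- stats::rgamma(5, shape = shape)
      d <- total[i] * w / sum(w)
      if (all(d <= 10)) {
        out[i, ] <- d
        break
      }
    }
    if (anyNA(out[i, ])) out[i, ] <- rep(total[i] / 5, 5)
  }
  out
}

#' Generate a synthetic cohort in a synthetic city
#'
#' Samples participant locations around the city's cluster seeds, computes
#' each participant's urban-quality index through the raster pipeline, and
#' draws clinical and laboratory variables from models calibrated to the
#' study conditions:
#'
#' 1. locations: cluster chosen by weight, scatter Normal(seed, cluster_sd)
#'    truncated to the grid extent;
#' 2. the summary index is computed at each location and standardized to `z`;
#' 3. frailty ~ Bernoulli(plogis(alpha + beta z)) with `alpha` from
#'    [calibrate_logistic_intercept()], so the cohort-mean frailty
#'    probability equals the target prevalence exactly;
#' 4. the latent FTS-5 total is drawn truncated to `[0, 25]` (non-frail) or
#'    `(25, 50]` (frail), so `frail <=> total > 25` holds by construction,
#'    and is split into the five domain scores;
#' 5. BMI and age are Normal per frailty group; handgrip and gait speed are
#'    linear in `z` with Gaussian noise;
#' 6. each analyte is drawn from a Gaussian copula with the index (latent
#'    correlation [spearman_to_pearson()] of its target) and mapped to its
#'    truncated-normal marginal;
#' 7. a uniform subsample of `n_lab_subset` participants is flagged as the
#'    laboratory subset (analytes are NA outside it).
#'
#' @param city A `uf_city` from [generate_city()].
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return A tibble of class `uf_cohort`, one row per participant, with
#'   attributes `index_raster` (the summary-index [raster_field()]),
#'   `quartile_edges`, `config` and `seed`.
#' @export
generate_cohort <- function(city, config = cohort_config(), seed) {
  stopifnot(inherits(city, "uf_city"), inherits(config, "cohort_config"))
  if (missing(seed)) stop("a seed is required (no silent entropy)", call. = FALSE)
  set.seed(derive_seed(seed, 1299709))
  n <- config$n_participants
  ext <- grid_extent(city$grid)
  ccfg <- city$config

  # 1. locations
  cl_draw <- sample.int(6, n, replace = TRUE, prob = ccfg$cluster_weights)
  x <- rtruncnorm(n, ccfg$cluster_centers[cl_draw, "x"], ccfg$cluster_sd,
                  ext["xmin"], ext["xmax"] - 1e-9)
  y <- rtruncnorm(n, ccfg$cluster_centers[cl_draw, "y"], ccfg$cluster_sd,
                  ext["ymin"], ext["ymax"] - 1e-9)
  pts <- tibble::tibble(participant_id = sprintf("P%03d", seq_len(n)), x = x, y = y)
  cluster <- cluster_at_points(city, pts)

  # 2. index via the raster pipeline
  surf <- urban_quality_surface(city$grid, city$layers)
  index <- extract_index_at_points(surf$index, pts)
  if (stats::sd(index) == 0) {
    stop("degenerate city: summary index is constant across participants",
         call. = FALSE)
  }
  z <- (index - mean(index)) / stats::sd(index)

  # 3. frailty status
  beta <- config$frailty_index_slope
  alpha <- calibrate_logistic_intercept(config$target_frailty_prevalence, beta, z)
  frail <- stats::runif(n) < stats::plogis(alpha + beta * z)

  # 4. FTS-5 total and domains (frail <=> total > 25 by construction)
  mu <- ifelse(frail, config$fts_frail[1], config$fts_nonfrail[1]) +
    config$fts_index_slope * z
  sdv <- ifelse(frail, config$fts_frail[2], config$fts_nonfrail[2])
  lower <- ifelse(frail, 25, 0)
  upper <- ifelse(frail, 50, 25)
  total <- rtruncnorm(n, mu, sdv, lower, upper)
  domains <- split_fts_domains(total, config$fts_split_shape)
  colnames(domains) <- unname(fts5_domains())

  # 5. demographics and physical performance
  bmi <- ifelse(frail,
                stats::rnorm(n, config$bmi_frail[1], config$bmi_frail[2]),
                stats::rnorm(n, config$bmi_nonfrail[1], config$bmi_nonfrail[2]))
  bmi <- pmin(pmax(bmi, 14), 55)
  age <- ifelse(frail,
                stats::rnorm(n, config$age_frail[1], config$age_frail[2]),
                stats::rnorm(n, config$age_nonfrail[1], config$age_nonfrail[2]))
  age <- pmax(age, 65)
  female <- stats::runif(n) <
    ifelse(frail, config$p_female_frail, config$p_female_nonfrail)
  handgrip <- config$handgrip_base + config$handgrip_slope * z +
    stats::rnorm(n, 0, config$handgrip_sd)
  handgrip <- pmax(handgrip, 2)
  gait <- config$gait_base + config$gait_slope * z +
    stats::rnorm(n, 0, config$gait_sd)
  gait <- pmax(gait, 0.2)

  # 6. laboratory analytes via a Gaussian copula with the index
  rk <- rank(index, ties.method = "average")
  zn <- stats::qnorm((rk - 0.5) / n)
  zn <- (zn - mean(zn)) / stats::sd(zn)
  labs <- tibble::tibble(.rows = n)
  for (j in seq_len(nrow(config$lab_panel))) {
    row <- config$lab_panel[j, ]
    rho_p <- spearman_to_pearson(row$rho_index)
    latent <- rho_p * zn + sqrt(1 - rho_p^2) * stats::rnorm(n)
    u <- stats::pnorm(latent)
    labs[[row$analyte]] <- qtruncnorm(u, row$mean, row$sd, row$lower, row$upper)
  }

  # 7. laboratory subset
  in_lab <- logical(n)
  in_lab[sample.int(n, config$n_lab_subset)] <- TRUE
  for (nm in names(labs)) labs[[nm]][!in_lab] <- NA_real_

  quart <- assign_quartiles(index)
  cohort <- dplyr::bind_cols(
    pts,
    tibble::tibble(
      cluster = cluster, index = index, index_z = z,
      quartile = as.character(quart), frail = frail,
      age = age, sex = ifelse(female, "female", "male"), bmi = bmi,
      handgrip_kg = handgrip, gait_speed_ms = gait
    ),
    tibble::as_tibble(domains),
    tibble::tibble(in_lab_subset = in_lab),
    labs
  )
  structure(
    cohort,
    class = c("uf_cohort", class(cohort)),
    index_raster = surf$index,
    quartile_edges = attr(quart, "edges"),
    config = config,
    seed = as.integer(seed)
  )
}

#' Simulate a full study: city plus cohort
#'
#' One-call wrapper generating the synthetic city and a cohort in it from a
#' single seed.
#'
#' @param seed Integer RNG seed.
#' @param city_config A [city_config()].
#' @param cohort_config A [cohort_config()].
#' @return A list of class `uf_study`: `city`, `cohort`, `seed`.
#' @examples
#' study <- simulate_study(seed = 1, cohort_config = cohort_config(n_participants = 40))
#' dplyr::count(study$cohort, frail = fts5_score(study$cohort)$frail)
#' @export
simulate_study <- function(seed, city_config = urbanfrailty::city_config(),
                           cohort_config = urbanfrailty::cohort_config()) {
  city <- generate_city(city_config, seed = seed)
  cohort <- generate_cohort(city, cohort_config, seed = seed)
  structure(list(city = city, cohort = cohort, seed = as.integer(seed)),
            class = "uf_study")
}

#' @export
print.uf_study <- function(x, ...) {
  cat(sprintf("<uf_study> seed %d: %d participants in a %s city\n",
              x$seed, nrow(x$cohort), format(x$city$grid)))
  invisible(x)
}

#' Calibrate the handgrip model by moment matching
#'
#' Grid-searches nothing: the handgrip model is linear in the standardized
#' index, so the quartile means are linear in (base, slope) given the
#' conditional means of `z` within the bottom and top index quartiles. Those
#' conditional means are estimated by simulating cohorts, after which base
#' and slope solve the two target equations exactly.
#'
#' @param q1_mean,q4_mean Target handgrip means (kg) in the bottom and top
#'   urban-quality quartiles (defaults 22.8 and 19.1).
#' @param n_seeds Number of simulated cohorts used to estimate the quartile
#'   z-means (default 50).
#' @param city_config,cohort_config Configurations used in the simulation.
#' @param seed Base seed for the simulated cohorts.
#' @return A list with `base`, `slope`, and the estimated `z_q1`, `z_q4`.
#' @export
calibrate_handgrip_slope <- function(q1_mean = 22.8, q4_mean = 19.1,
                                     n_seeds = 50,
                                     city_config = urbanfrailty::city_config(),
                                     cohort_config = urbanfrailty::cohort_config(),
                                     seed = 1) {
  z1 <- z4 <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    st <- simulate_study(seed + k - 1, city_config, cohort_config)
    z <- st$cohort$index_z
    q <- st$cohort$quartile
    z1[k] <- mean(z[q == "Q1"])
    z4[k] <- mean(z[q == "Q4"])
  }
  z_q1 <- mean(z1)
  z_q4 <- mean(z4)
  slope <- (q4_mean - q1_mean) / (z_q4 - z_q1)
  base <- q1_mean - slope * z_q1
  list(base = base, slope = slope, z_q1 = z_q1, z_q4 = z_q4)
}
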