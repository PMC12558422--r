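#' FTS-5 domain names and their cohort columns
#'
#' The Frailty Trait Scale 5 (FTS-5) assesses five domains — nutrition,
#' physical activity, nervous system, strength and gait speed — each scored
#' 0 to 10. The cohort table stores them in the columns returned here.
#'
#' @return Named character vector mapping domain names to cohort column names.
#' @export
fts5_domains <- function() {
  c(
    nutrition = "fts_nutrition",
    physical_activity = "fts_pa",
    nervous_system = "fts_nervous",
    strength = "fts_strength",
    gait_speed = "fts_gait"
  )
}

#' Default FTS-3 domain subset
#'
#' The shortened FTS-3 sums three of the five FTS-5 domains. The instrument's
#' exact composition varies between deployments, so the subset is
#' configurable; the default uses the three physical-performance domains.
#'
#' @return Character vector of three domain names.
#' @export
fts3_default_subset <- function() {
  c("physical_activity", "strength", "gait_speed")
}

check_fts_domains <- function(data, cols) {
  missing <- setdiff(unname(cols), names(data))
  if (length(missing)) {
    stop("missing FTS domain column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(cols)) {
    v <- data[[cols[[nm]]]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 10)) {
      stop(sprintf("FTS-5 domain '%s' has values outside [0, 10]", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Score the FTS-5 frailty scale
#'
#' Sums the five FTS-5 domain scores (each 0-10) into a total on 0-50 and
#' classifies frailty: a total strictly above the threshold (default 25) is
#' frail; a total of exactly 25 is not.
#'
#' @param data A data frame with the five domain columns (see
#'   [fts5_domains()]).
#' @param threshold Frailty cut-off on the total score (default 25; frail
#'   means total > threshold).
#' @param domain_cols Named character vector mapping the five domain names to
#'   columns of `data`; defaults to [fts5_domains()].
#' @return `data` as a tibble with `fts5_total` and logical `frail` appended.
#' @examples
#' fts5_score(data.frame(
#'   fts_nutrition = 5, fts_pa = 5, fts_nervous = 5,
#'   fts_strength = 5, fts_gait = c(5, 6)
#' ))
#' @export
fts5_score <- function(data, threshold = 25, domain_cols = fts5_domains()) {
  data <- tibble::as_tibble(data)
  check_fts_domains(data, domain_cols)
  total <- Reduce(`+`, lapply(unname(domain_cols), function(cl) data[[cl]]))
  data$fts5_total <- total
  data$frail <- total > threshold
  data
}

#' Score an FTS subscale
#'
#' Sums a subset of FTS-5 domains (e.g. the FTS-3 short form). No frailty
#' classification is attached: the frailty cut-off is defined for the full
#' five-domain total only.
#'
#' @param data A data frame holding the required domain columns.
#' @param subset Character vector of domain names (see [fts5_domains()]);
#'   defaults to the FTS-3 subset.
#' @param name Name of the appended column (default `"fts3"`).
#' @inheritParams fts5_score
#' @return `data` as a tibble with the subscale column appended.
#' @export
fts_subscale <- function(data, subset = fts3_default_subset(), name = "fts3",
                         domain_cols = fts5_domains()) {
  if (length(subset) == 0) stop("subset must be non-empty", call. = FALSE)
  unknown <- setdiff(subset, names(domain_cols))
  if (length(unknown)) {
    stop("unknown FTS domain name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(subset)) {
    stop("duplicate FTS domain name(s) in subset", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  cols <- domain_cols[subset]
  check_fts_domains(data, cols)
  data[[name]] <- Reduce(`+`, lapply(unname(cols), function(cl) data[[cl]]))
  data
}

#' Default CONUT scoring bands
#'
#' The CONUT (Controlling Nutritional Status) score grades three analytes.
#' Each band is given as the lower edges of the subscore intervals, scanned
#' from the healthiest band down:
#' albumin (g/dL) >= 3.50 -> 0, 3.00-3.49 -> 2, 2.50-2.99 -> 4, < 2.50 -> 6;
#' lymphocytes (cells/mm3) >= 1600 -> 0, 1200-1599 -> 1, 800-1199 -> 2,
#' < 800 -> 3; total cholesterol (mg/dL) >= 180 -> 0, 140-179 -> 1,
#' 100-139 -> 2, < 100 -> 3.
#'
#' All edges are configurable so that simplified single-cutoff variants can be
#' reproduced by collapsing bands.
#'
#' @return A list with elements `albumin`, `lymphocytes`, `cholesterol`, each
#'   a list of `edges` (descending lower edges of the healthy-to-worst bands)
#'   and `scores` (subscore per band, same length plus one for values below
#'   the last edge).
#' @export
conut_bands <- function() {
  list(
    albumin = list(edges = c(3.50, 3.00, 2.50), scores = c(0L, 2L, 4L, 6L)),
    lymphocytes = list(edges = c(1600, 1200, 800), scores = c(0L, 1L, 2L, 3L)),
    cholesterol = list(edges = c(180, 140, 100), scores = c(0L, 1L, 2L, 3L))
  )
}

# Band lookup: first band whose lower edge the value reaches; below every
# edge -> last (worst) score. Exhaustive and non-overlapping by construction.
conut_subscore <- function(value, band) {
  score <- rep(band$scores[length(band$scores)], length(value))
  for (k in rev(seq_along(band$edges))) {
    score[value >= band$edges[k]] <- band$scores[k]
  }
  score
}

#' CONUT malnutrition category from the total score
#'
#' @param total Integer CONUT total(s) in 0-12.
#' @return Factor with levels `normal` (0-1), `light` (2-4), `moderate` (5-8),
#'   `severe` (>= 9).
#' @export
conut_category <- function(total) {
  if (any(!is.finite(total)) || any(total < 0) || any(total > 12)) {
    stop("CONUT totals must lie in [0, 12]", call. = FALSE)
  }
  cut(total, breaks = c(-Inf, 1, 4, 8, Inf),
      labels = c("normal", "light", "moderate", "severe"))
}

#' Score nutritional status with CONUT
#'
#' Computes the CONUT score from serum albumin, total lymphocyte count and
#' total cholesterol: each analyte maps to a graded subscore (see
#' [conut_bands()]), the subscores sum to a 0-12 total, and the total maps to
#' a malnutrition category via [conut_category()]. Rows with any required
#' analyte missing (NA) get NA scores; absent columns are an error.
#'
#' @param data A data frame with numeric columns `albumin` (g/dL),
#'   `lymphocytes` (cells/mm3) and `cholesterol` (mg/dL).
#' @param bands Banding configuration as returned by [conut_bands()].
#' @return `data` as a tibble with `albumin_sub`, `lymphocyte_sub`,
#'   `cholesterol_sub`, `conut_total` and `conut_category` appended.
#' @examples
#' conut_score(data.frame(albumin = c(4.2, 2.4), lymphocytes = c(2000, 700),
#'                        cholesterol = c(200, 90)))
#' @export
conut_score <- function(data, bands = conut_bands()) {
  data <- tibble::as_tibble(data)
  needed <- c("albumin", "lymphocytes", "cholesterol")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("missing required analyte column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) {
    v <- data[[nm]]
    if (any(v < 0, na.rm = TRUE)) {
      stop(sprintf("analyte '%s' has negative values", nm), call. = FALSE)
    }
  }
  ok <- stats::complete.cases(data[needed])
  sub <- function(nm) {
    out <- rep(NA_integer_, nrow(data))
    out[ok] <- conut_subscore(data[[nm]][ok], bands[[nm]])
    out
  }
  data$albumin_sub <- sub("albumin")
  data$lymphocyte_sub <- sub("lymphocytes")
  data$cholesterol_sub <- sub("cholesterol")
  data$conut_total <- data$albumin_sub + data$lymphocyte_sub +
    data$cholesterol_sub
  data$conut_category <- factor(rep(NA_character_, nrow(data)),
                                levels = c("normal", "light", "moderate", "severe"))
  data$conut_category[ok] <- conut_category(data$conut_total[ok])
  data
}
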