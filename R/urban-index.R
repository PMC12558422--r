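#' The seven urban facility types
#'
#' The urban-quality summary index aggregates proximity to seven kinds of
#' facility relevant to older adults: fresh-food shops, senior centres,
#' pharmacies, emergency health centres, squares and parks, family/community
#' health centres, and exercise facilities.
#'
#' @return Character vector of the seven facility type codes.
#' @export
facility_types <- function() {
  c(
    "vegetables_fruits", "senior_centers", "pharmacies", "emergency_health",
    "squares_parks", "family_health", "exercise_facilities"
  )
}

#' Distance bands for proximity scoring
#'
#' Each facility type carries two distance thresholds that split the city into
#' three access zones: close (`d < near_max`, score 3), medium
#' (`near_max <= d <= mid_max`, score 2) and distant (`d > mid_max`, score 1).
#' Boundary distances fall in the medium zone, following the strict
#' inequalities that define the close and distant zones.
#'
#' @param near_max,mid_max Zone thresholds in metres, `0 < near_max < mid_max`.
#' @return An object of class `distance_bands`.
#' @export
distance_bands <- function(near_max, mid_max) {
  if (!is.finite(near_max) || !is.finite(mid_max) ||
      near_max <= 0 || mid_max <= near_max) {
    stop("distance bands require 0 < near_max < mid_max", call. = FALSE)
  }
  structure(list(near_max = as.numeric(near_max), mid_max = as.numeric(mid_max)),
            class = "distance_bands")
}

#' @export
print.distance_bands <- function(x, ...) {
  cat(sprintf("<distance_bands> <%g m -> 3; %g-%g m -> 2; >%g m -> 1\n",
              x$near_max, x$near_max, x$mid_max, x$mid_max))
  invisible(x)
}

#' Default distance bands per facility type
#'
#' Access-effort thresholds for each of the seven facility types: fresh-food
#' shops 300/600 m, senior centres 500/1000 m, pharmacies 500/1000 m,
#' emergency health centres 1000/2000 m, squares and parks 200/400 m,
#' family health centres 700/1400 m, exercise facilities 400/600 m.
#'
#' @param facility_type Optional single facility type; if given, the
#'   corresponding [distance_bands()] object is returned instead of the table.
#' @return A tibble (`facility_type`, `near_max`, `mid_max`) or a
#'   [distance_bands()] object.
#' @examples
#' default_distance_bands()
#' default_distance_bands("squares_parks")
#' @export
default_distance_bands <- function(facility_type = NULL) {
  tbl <- tibble::tibble(
    facility_type = facility_types(),
    near_max = c(300, 500, 500, 1000, 200, 700, 400),
    mid_max = c(600, 1000, 1000, 2000, 400, 1400, 600)
  )
  if (is.null(facility_type)) return(tbl)
  facility_type <- match.arg(facility_type, facility_types())
  row <- tbl[tbl$facility_type == facility_type, ]
  distance_bands(row$near_max, row$mid_max)
}

#' Construct a facility layer
#'
#' A facility layer is a typed set of point locations (planar metres) together
#' with the distance bands used to score proximity to it.
#'
#' @param facility_type One of [facility_types()].
#' @param points A data frame with numeric columns `x` and `y` (metres).
#' @param bands A [distance_bands()] object; defaults to the type's standard
#'   bands.
#' @return An object of class `facility_layer`.
#' @export
facility_layer <- function(facility_type, points,
                           bands = default_distance_bands(facility_type)) {
  facility_type <- match.arg(facility_type, facility_types())
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop("points must have columns x and y", call. = FALSE)
  }
  if (nrow(points) == 0) stop("no facility points", call. = FALSE)
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop("facility coordinates must be finite", call. = FALSE)
  }
  stopifnot(inherits(bands, "distance_bands"))
  structure(
    list(facility_type = facility_type,
         points = points[, c("x", "y")], bands = bands),
    class = "facility_layer"
  )
}

#' @export
print.facility_layer <- function(x, ...) {
  cat(sprintf("<facility_layer> %s: %d points, bands %g/%g m\n",
              x$facility_type, nrow(x$points),
              x$bands$near_max, x$bands$mid_max))
  invisible(x)
}

# Exact Euclidean nearest-neighbour distance from (x, y) to the layer points.
# Iterates over points keeping a running squared minimum: exact, vectorised in
# the query points, and memory-linear in their number.
nearest_point_distance <- function(x, y, px, py) {
  best <- rep(Inf, length(x))
  for (k in seq_along(px)) {
    d2 <- (x - px[k])^2 + (y - py[k])^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Euclidean distance surface to the nearest facility
#'
#' Computes, for every grid cell, the exact straight-line distance (metres)
#' from the cell centre to the nearest point of the facility layer. No
#' approximate distance transform is used: the surface equals the brute-force
#' minimum over all facility points at every cell.
#'
#' @param grid A [grid_spec()].
#' @param layer A [facility_layer()] with at least one point.
#' @return A [raster_field()] of kind `"distance"`.
#' @examples
#' g <- grid_spec(n_rows = 4, n_cols = 4, cell_size = 50)
#' lay <- facility_layer("pharmacies", data.frame(x = 100, y = 100))
#' compute_distance_raster(g, lay)
#' @export
compute_distance_raster <- function(grid, layer) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!inherits(layer, "facility_layer") || nrow(layer$points) == 0) {
    stop("no facility points", call. = FALSE)
  }
  cc <- cell_centers(grid)
  d <- nearest_point_distance(cc$x, cc$y, layer$points$x, layer$points$y)
  raster_field(grid, matrix(d, grid$n_rows, grid$n_cols), kind = "distance")
}

#' Reclassify distance into a proximity score
#'
#' Maps a distance to the 3-zone proximity score: `d < near_max` scores 3
#' (close), `near_max <= d <= mid_max` scores 2 (medium), `d > mid_max`
#' scores 1 (distant). Higher scores mean better access.
#'
#' @param d Distance(s) in metres, non-negative.
#' @param bands A [distance_bands()] object.
#' @return Integer score(s) in `{1, 2, 3}`.
#' @examples
#' classify_distance(c(100, 300, 600, 601), default_distance_bands("vegetables_fruits"))
#' @export
classify_distance <- function(d, bands) {
  stopifnot(inherits(bands, "distance_bands"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  ifelse(d < bands$near_max, 3L, ifelse(d > bands$mid_max, 1L, 2L))
}

#' Score a distance surface
#'
#' Applies [classify_distance()] cellwise to a distance raster, producing the
#' facility's proximity-score layer.
#'
#' @param distance A [raster_field()] of kind `"distance"`.
#' @param bands A [distance_bands()] object.
#' @param facility_type Optional facility type tag carried on the result (used
#'   by [summary_index()] to reject duplicated layers).
#' @return A [raster_field()] of kind `"score"`.
#' @export
score_raster <- function(distance, bands, facility_type = NULL) {
  stopifnot(inherits(distance, "raster_field"))
  if (distance$kind != "distance") {
    stop("score_raster expects a distance raster", call. = FALSE)
  }
  vals <- classify_distance(as.vector(distance$values), bands)
  out <- raster_field(distance$grid,
                      matrix(vals, distance$grid$n_rows, distance$grid$n_cols),
                      kind = "score")
  attr(out, "facility_type") <- facility_type
  out
}

#' Sum score layers into the urban-quality summary index
#'
#' The summary index is the cellwise sum of the per-facility proximity-score
#' layers; with the full set of 7 layers every cell lies in `[7, 21]`, and
#' higher values reflect better urban quality. All layers must share one grid
#' and no facility type may appear twice.
#'
#' @param score_rasters A list of score [raster_field()]s, one per facility
#'   type (as produced by [score_raster()]). A named list is taken as named by
#'   facility type when the rasters carry no tag of their own.
#' @return A [raster_field()] of kind `"index"` with `n_layers` set to the
#'   number of layers summed.
#' @export
summary_index <- function(score_rasters) {
  if (!is.list(score_rasters) || length(score_rasters) == 0) {
    stop("summary_index needs a non-empty list of score rasters", call. = FALSE)
  }
  types <- purrr::imap_chr(score_rasters, function(r, nm) {
    if (!inherits(r, "raster_field") || r$kind != "score") {
      stop("summary_index expects score rasters", call. = FALSE)
    }
    tag <- attr(r, "facility_type")
    if (!is.null(tag)) tag else if (is.character(nm) && nzchar(nm)) nm else NA_character_
  })
  known <- types[!is.na(types)]
  if (anyDuplicated(known)) {
    stop("duplicate facility type in score layers: ",
         paste(unique(known[duplicated(known)]), collapse = ", "),
         call. = FALSE)
  }
  grid <- score_rasters[[1]]$grid
  for (r in score_rasters[-1]) {
    if (!grid_equal(grid, r$grid)) {
      stop("score rasters are on mismatched grids", call. = FALSE)
    }
  }
  total <- Reduce(`+`, lapply(score_rasters, `[[`, "values"))
  raster_field(grid, total, kind = "index", n_layers = length(score_rasters))
}

#' Extract index values at point locations
#'
#' Performs the spatial join between an index surface and point locations:
#' each point receives the value of the cell that contains it (half-open cell
#' extents, no interpolation), so a point on a shared cell edge is assigned
#' deterministically to one cell.
#'
#' @param index A [raster_field()] (any kind; typically the summary index).
#' @param points A data frame with columns `x`, `y` and optionally an id
#'   column named `participant_id` or `id` (used in error messages).
#' @return Numeric vector of cell values, one per point.
#' @export
extract_index_at_points <- function(index, points) {
  stopifnot(inherits(index, "raster_field"))
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop("points must have columns x and y", call. = FALSE)
  }
  ids <- points[["participant_id"]] %||% points[["id"]]
  cell <- point_to_cell(index$grid, points$x, points$y, ids = ids)
  index$values[cbind(cell$row, cell$col)]
}

#' Assign empirical quartiles of the summary index
#'
#' Participants are stratified by the empirical quartiles of their index
#' values: Q1 is the lowest-index quarter (poorest urban quality) and Q4 the
#' highest. Bins above Q1 are right-closed (`Qk = (e_{k-1}, e_k]`, Q1 =
#' `[min, e_25]`), so tied values always share a bin.
#'
#' @param values Numeric vector of at least 4 index values.
#' @return A factor with levels `Q1`-`Q4` and an attribute `edges` holding the
#'   25/50/75th empirical percentiles. If all values coincide the edges are
#'   degenerate, every value falls in Q1, and a warning is raised.
#' @export
assign_quartiles <- function(values) {
  if (any(!is.finite(values))) stop("index values must be finite", call. = FALSE)
  if (length(values) < 4) {
    stop("at least 4 values are needed to form quartiles", call. = FALSE)
  }
  edges <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE)
  if (edges[1] == edges[3]) {
    warning("degenerate quartile edges: index values are (almost) constant",
            call. = FALSE)
  }
  lab <- rep("Q1", length(values))
  lab[values > edges[1]] <- "Q2"
  lab[values > edges[2]] <- "Q3"
  lab[values > edges[3]] <- "Q4"
  structure(factor(lab, levels = c("Q1", "Q2", "Q3", "Q4")), edges = edges)
}

#' Exact distance from points to the nearest facility
#'
#' Per-point Euclidean distance (metres) to the nearest point of a facility
#' layer, computed directly on coordinates (not via the raster), as used when
#' comparing facility access between frail and non-frail participants.
#'
#' @param points A data frame with columns `x`, `y`.
#' @param layer A [facility_layer()].
#' @return Numeric vector of distances, one per point.
#' @examples
#' distance_to_nearest(data.frame(x = 0, y = 0),
#'   facility_layer("pharmacies", data.frame(x = c(3, 10), y = c(4, 0))))
#' @export
distance_to_nearest <- function(points, layer) {
  if (!inherits(layer, "facility_layer") || nrow(layer$points) == 0) {
    stop("no facility points", call. = FALSE)
  }
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    stop("points must have columns x and y", call. = FALSE)
  }
  nearest_point_distance(points$x, points$y, layer$points$x, layer$points$y)
}

#' Per-participant distances to every facility type
#'
#' @param points A data frame with `x`, `y` and optionally `participant_id`.
#' @param layers A named list of [facility_layer()]s.
#' @return A tibble with `participant_id` (if present) and one
#'   `dist_<facility_type>` column per layer.
#' @export
participant_distances <- function(points, layers) {
  points <- tibble::as_tibble(points)
  out <- if ("participant_id" %in% names(points)) {
    points["participant_id"]
  } else {
    tibble::tibble(.rows = nrow(points))
  }
  for (nm in names(layers)) {
    out[[paste0("dist_", layers[[nm]]$facility_type)]] <-
      distance_to_nearest(points, layers[[nm]])
  }
  out
}

#' Build the full urban-quality surface for a city
#'
#' Convenience wrapper running distance surface -> proximity score for every
#' facility layer and summing into the summary index.
#'
#' @param grid A [grid_spec()].
#' @param layers A list of [facility_layer()]s (at most one per type).
#' @return A list with `distance` (named list of distance rasters), `score`
#'   (named list of score rasters) and `index` (the summary index raster).
#' @export
urban_quality_surface <- function(grid, layers) {
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- vapply(layers, `[[`, "", "facility_type")
  }
  distance <- purrr::map(layers, ~ compute_distance_raster(grid, .x))
  score <- purrr::map2(distance, layers,
                       ~ score_raster(.x, .y$bands, .y$facility_type))
  list(distance = distance, score = score, index = summary_index(score))
}
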