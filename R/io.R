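#' Write a facility layer as GeoJSON
#'
#' Serializes a facility layer as a GeoJSON FeatureCollection of Point
#' features, each carrying a `facility_type` property, with the layer's
#' distance bands and the coordinate frame tag stored in top-level
#' `properties`. Coordinates are planar metres in the local frame (no CRS
#' transformation is ever applied).
#'
#' @param layer A [facility_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_facility_geojson <- function(layer, path) {
  stopifnot(inherits(layer, "facility_layer"))
  features <- purrr::pmap(layer$points, function(x, y) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(x, y)),
      properties = list(facility_type = layer$facility_type)
    )
  })
  obj <- list(
    type = "FeatureCollection",
    properties = list(
      facility_type = layer$facility_type,
      near_max = layer$bands$near_max, mid_max = layer$bands$mid_max
    ),
    features = features
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a facility layer from GeoJSON
#'
#' Accepts a FeatureCollection of Point features. Every feature must be a
#' Point (the index of the first offending feature is reported otherwise) and
#' the facility type — from the collection-level `properties` or the first
#' feature's — must be one of [facility_types()].
#'
#' @param path A GeoJSON file written by [write_facility_geojson()] or
#'   equivalent.
#' @return A [facility_layer()].
#' @export
read_facility_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  geom_types <- vapply(obj$features, function(f) f$geometry$type %||% "", "")
  bad <- which(geom_types != "Point")
  if (length(bad)) {
    stop(sprintf("non-Point geometry '%s' at feature %d",
                 geom_types[bad[1]], bad[1]), call. = FALSE)
  }
  ft <- obj$properties$facility_type %||%
    obj$features[[1]]$properties$facility_type
  if (is.null(ft) || !ft %in% facility_types()) {
    stop("unknown facility_type: ", ft %||% "<missing>", call. = FALSE)
  }
  pts <- purrr::map_dfr(obj$features, function(f) {
    tibble::tibble(x = as.numeric(f$geometry$coordinates[[1]]),
                   y = as.numeric(f$geometry$coordinates[[2]]))
  })
  bands <- if (!is.null(obj$properties$near_max)) {
    distance_bands(obj$properties$near_max, obj$properties$mid_max)
  } else {
    default_distance_bands(ft)
  }
  facility_layer(ft, pts, bands)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS software:
#' a 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize, nodata)
#' followed by rows of values, top row first.
#'
#' @param raster A [raster_field()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel written in the header (default -9999; score
#'   and index rasters never contain it since their valid values start at 1).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "raster_field"))
  g <- raster$grid
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  # ASCII grids are written north to south: last matrix row first
  rows <- apply(raster$values[rev(seq_len(g$n_rows)), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path An `.asc` file as written by [write_ascii_grid()].
#' @param kind Raster kind of the result (default `"index"`).
#' @param n_layers Number of layers for an index raster (default 7).
#' @return A [raster_field()].
#' @export
read_ascii_grid <- function(path, kind = "index", n_layers = 7L) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  hv <- setNames(
    vapply(hdr, function(h) as.numeric(h[2]), 0),
    tolower(vapply(hdr, `[[`, "", 1))
  )
  g <- grid_spec(
    n_rows = hv[["nrows"]], n_cols = hv[["ncols"]],
    cell_size = hv[["cellsize"]],
    origin_x = hv[["xllcorner"]], origin_y = hv[["yllcorner"]]
  )
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  raster_field(g, vals[rev(seq_len(g$n_rows)), , drop = FALSE],
               kind = kind, n_layers = n_layers)
}

#' Write a city bundle
#'
#' Writes a synthetic city to a directory: one GeoJSON file per facility
#' layer, a `grid.json` with the grid specification, and `clusters.asc` with
#' the cluster partition.
#'
#' @param city A `uf_city` from [generate_city()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_city_bundle <- function(city, dir) {
  stopifnot(inherits(city, "uf_city"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ft in names(city$layers)) {
    write_facility_geojson(city$layers[[ft]], file.path(dir, paste0(ft, ".geojson")))
  }
  jsonlite::write_json(
    city$grid[c("origin_x", "origin_y", "cell_size", "n_rows", "n_cols", "crs")],
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = 10
  )
  cl <- raster_field(city$grid, city$clusters, kind = "distance")
  write_ascii_grid(cl, file.path(dir, "clusters.asc"))
  invisible(dir)
}

#' Read a city bundle
#'
#' Reads the grid and facility layers written by [write_city_bundle()]. If
#' some of the 7 facility types are absent a warning reports that the
#' summary index computed from the bundle will span `[n, 3n]` for the `n`
#' layers found.
#'
#' @param dir Directory holding `grid.json` and `<facility_type>.geojson`
#'   files.
#' @return A list of class `uf_city` with `grid`, `layers` and (if present)
#'   `clusters`.
#' @export
read_city_bundle <- function(dir) {
  gpath <- file.path(dir, "grid.json")
  if (!file.exists(gpath)) stop("grid.json not found in ", dir, call. = FALSE)
  gj <- jsonlite::read_json(gpath)
  grid <- grid_spec(
    n_rows = gj$n_rows, n_cols = gj$n_cols, cell_size = gj$cell_size,
    origin_x = gj$origin_x, origin_y = gj$origin_y, crs = gj$crs %||% "local-metres"
  )
  layers <- list()
  for (ft in facility_types()) {
    p <- file.path(dir, paste0(ft, ".geojson"))
    if (file.exists(p)) layers[[ft]] <- read_facility_geojson(p)
  }
  if (length(layers) == 0) stop("no facility layers found in ", dir, call. = FALSE)
  if (length(layers) < length(facility_types())) {
    warning(sprintf(
      "only %d of %d facility layers present; summary index will span [%d, %d]",
      length(layers), length(facility_types()), length(layers), 3 * length(layers)
    ), call. = FALSE)
  }
  clusters <- NULL
  cpath <- file.path(dir, "clusters.asc")
  if (file.exists(cpath)) {
    clusters <- read_ascii_grid(cpath, kind = "distance")$values
    storage.mode(clusters) <- "integer"
  }
  structure(
    list(grid = grid, layers = layers, clusters = clusters,
         cluster_centers = NULL, config = NULL, seed = NA_integer_),
    class = "uf_city"
  )
}

#' Write / read a cohort CSV
#'
#' Cohort tables round-trip through plain CSV; the writer emits a stable
#' column order and full precision so identical cohorts produce byte-identical
#' files.
#'
#' @param cohort A cohort tibble.
#' @param path CSV file path.
#' @return `path` (writer, invisibly) or the cohort tibble (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Flatten an uf_report into plain lists for JSON serialization.
report_to_list <- function(report) {
  stopifnot(inherits(report, "uf_report"))
  unclassed <- function(x) {
    if (inherits(x, "tbl_df")) as.data.frame(x) else x
  }
  list(
    table2 = unclassed(report$table2),
    table3 = list(cells = unclassed(report$table3$cells),
                  tests = unclassed(report$table3$tests)),
    table4 = unclassed(report$table4),
    fig3 = unclassed(report$fig3),
    fig4 = purrr::map(report$fig4, unclassed),
    fig6 = if (!is.null(report$fig6)) purrr::map(report$fig6, unclassed),
    meta = report$meta
  )
}

#' Serialize a report to JSON
#'
#' @param report A `uf_report` from [build_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)
  invisible(path)
}
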