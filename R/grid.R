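#' Define a planar raster grid
#'
#' A grid specification describes a regular raster in a local projected frame
#' with planar metre coordinates: an origin (lower-left corner), a square cell
#' size, and the number of rows and columns. Cell centres sit at
#' `origin + (i + 0.5) * cell_size`; cell extents are half-open, so a point on
#' a shared edge belongs to exactly one cell.
#'
#' @param n_rows,n_cols Number of rows / columns (positive integers). Rows run
#'   south to north, columns west to east.
#' @param cell_size Cell edge length in metres (default 50, the resolution at
#'   which the summary index surface is computed).
#' @param origin_x,origin_y Coordinates of the grid's lower-left corner, in
#'   metres.
#' @param crs Free-text coordinate reference tag carried as metadata. The
#'   package never reprojects; all geometry is Euclidean in the given frame.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(n_rows = 100, n_cols = 100)
#' g
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 50, origin_x = 0,
                      origin_y = 0, crs = "local-metres") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a positive number of metres", call. = FALSE)
  }
  if (!is.finite(origin_x) || !is.finite(origin_y)) {
    stop("grid origin must be finite", call. = FALSE)
  }
  structure(
    list(
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size), n_rows = n_rows, n_cols = n_cols,
      crs = as.character(crs)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$cell_size)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a[c("origin_x", "origin_y", "cell_size")],
                   b[c("origin_x", "origin_y", "cell_size")])) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

grid_extent <- function(grid) {
  c(
    xmin = grid$origin_x, xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y, ymax = grid$origin_y + grid$n_rows * grid$cell_size
  )
}

#' Cell centres of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y` (centre
#'   coordinates in metres), in column-major order (column 1 south-to-north
#'   first).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- seq_len(grid$n_rows)
  cols <- seq_len(grid$n_cols)
  tibble::tibble(
    row = rep(rows, times = grid$n_cols),
    col = rep(cols, each = grid$n_rows),
    x = grid$origin_x + (rep(cols, each = grid$n_rows) - 0.5) * grid$cell_size,
    y = grid$origin_y + (rep(rows, times = grid$n_cols) - 0.5) * grid$cell_size
  )
}

# Map points to (row, col); half-open extents [x0, x0 + cs) so edge points are
# assigned to exactly one cell. Errors list the offending point ids.
point_to_cell <- function(grid, x, y, ids = NULL) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  if (any(bad)) {
    if (is.null(ids)) ids <- seq_along(x)
    stop(
      "points outside grid extent: ",
      paste(utils::head(ids[bad], 10), collapse = ", "),
      if (sum(bad) > 10) sprintf(" (and %d more)", sum(bad) - 10L),
      call. = FALSE
    )
  }
  list(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster field
#'
#' A raster field couples a [grid_spec()] with an `n_rows x n_cols` value
#' matrix and a `kind` tag that fixes the admissible values: `"distance"`
#' surfaces are non-negative metres, `"score"` surfaces take the proximity
#' scores 1/2/3, and `"index"` surfaces are integer sums of score layers in
#' `[n_layers, 3 * n_layers]`.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix, `grid$n_rows` rows by `grid$n_cols` columns.
#'   Row `i` covers the band of y-coordinates `origin_y + (i-1..i) * cell_size`.
#' @param kind One of `"distance"`, `"score"`, `"index"`.
#' @param n_layers For `kind = "index"`, the number of score layers summed
#'   (defaults to 7, the full facility set).
#' @return An object of class `raster_field`.
#' @seealso [compute_distance_raster()], [summary_index()], [as_tibble()]
#' @export
raster_field <- function(grid, values, kind = c("distance", "score", "index"),
                         n_layers = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols))) {
    stop(sprintf(
      "values must be a %d x %d matrix to match the grid",
      grid$n_rows, grid$n_cols
    ), call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("raster values must not contain NA", call. = FALSE)
  if (kind == "distance" && any(values < 0)) {
    stop("distance raster values must be >= 0", call. = FALSE)
  }
  if (kind == "score" && !all(values %in% c(1, 2, 3))) {
    stop("score raster values must be in {1, 2, 3}", call. = FALSE)
  }
  if (kind == "index") {
    if (is.null(n_layers)) n_layers <- 7L
    n_layers <- as.integer(n_layers)
    if (any(values != round(values)) ||
        any(values < n_layers) || any(values > 3L * n_layers)) {
      stop(sprintf(
        "index raster values must be integers in [%d, %d]",
        n_layers, 3L * n_layers
      ), call. = FALSE)
    }
  }
  structure(
    list(grid = grid, values = values, kind = kind,
         n_layers = if (kind == "index") n_layers else NULL),
    class = "raster_field"
  )
}

#' @export
print.raster_field <- function(x, ...) {
  cat(sprintf(
    "<raster_field: %s> %s, values in [%g, %g]\n",
    x$kind, format(x$grid), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Flatten a raster field to a tibble
#'
#' @param x A [raster_field()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y` (cell centres) and `value`.
#' @importFrom tibble as_tibble
#' @method as_tibble raster_field
#' @export
as_tibble.raster_field <- function(x, ...) {
  out <- cell_centers(x$grid)
  out$value <- as.vector(x$values)
  out
}
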