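test_that("distance raster is exact for coincident and axis-aligned points", {
  g1 <- grid_spec(n_rows = 1, n_cols = 1, cell_size = 50)
  lay <- facility_layer("pharmacies", data.frame(x = 25, y = 25))
  expect_equal(compute_distance_raster(g1, lay)$values[1, 1], 0)

  g2 <- grid_spec(n_rows = 1, n_cols = 2, cell_size = 50)
  d <- compute_distance_raster(g2, lay)
  expect_equal(as.vector(d$values), c(0, 50))
})

test_that("distance raster equals the brute-force oracle on random grids", {
  set.seed(42)
  for (rep in 1:3) {
    g <- grid_spec(n_rows = 20, n_cols = 20, cell_size = 50)
    pts <- data.frame(x = runif(5, 0, 1000), y = runif(5, 0, 1000))
    lay <- facility_layer("squares_parks", pts)
    got <- compute_distance_raster(g, lay)
    cc <- cell_centers(g)
    expect_equal(as.vector(got$values),
                 oracle_nearest(cc$x, cc$y, pts$x, pts$y))
  }
})

test_that("empty facility layers are rejected", {
  expect_error(facility_layer("pharmacies", data.frame(x = numeric(), y = numeric())),
               "no facility points")
  expect_error(distance_to_nearest(data.frame(x = 0, y = 0), structure(
    list(points = data.frame()), class = "facility_layer"
  )), "no facility points")
})

test_that("distance classification follows the band boundaries", {
  veg <- default_distance_bands("vegetables_fruits")
  expect_identical(classify_distance(100, veg), 3L)
  expect_identical(classify_distance(300, veg), 2L) # boundary -> middle band
  expect_identical(classify_distance(600, veg), 2L)
  expect_identical(classify_distance(601, veg), 1L)
  er <- default_distance_bands("emergency_health")
  expect_identical(classify_distance(2500, er), 1L)
  expect_error(classify_distance(-1, veg), ">= 0")
})

test_that("classification is non-increasing in distance", {
  for (ft in facility_types()) {
    b <- default_distance_bands(ft)
    d <- seq(0, 3000, by = 10)
    s <- classify_distance(d, b)
    expect_true(all(diff(s) <= 0))
  }
})

test_that("summary index sums layers and enforces bounds", {
  g <- grid_spec(n_rows = 2, n_cols = 2, cell_size = 50)
  mk <- function(v, ft) {
    score_raster(
      raster_field(g, matrix(0, 2, 2), kind = "distance"),
      distance_bands(1, 2), ft
    ) |> (\(r) { r$values[] <- v; r })()
  }
  all3 <- lapply(seq_along(facility_types()),
                 function(i) mk(3, facility_types()[i]))
  expect_true(all(summary_index(all3)$values == 21))
  all1 <- lapply(seq_along(facility_types()),
                 function(i) mk(1, facility_types()[i]))
  expect_true(all(summary_index(all1)$values == 7))
  two <- list(mk(3, "pharmacies"), mk(2, "senior_centers"))
  expect_true(all(summary_index(two)$values == 5))

  expect_error(summary_index(list(mk(3, "pharmacies"), mk(2, "pharmacies"))),
               "duplicate facility type")
  g2 <- grid_spec(n_rows = 3, n_cols = 2, cell_size = 50)
  other <- score_raster(raster_field(g2, matrix(0, 3, 2), kind = "distance"),
                        distance_bands(1, 2), "senior_centers")
  expect_error(summary_index(list(mk(3, "pharmacies"), other)), "mismatched grids")
})

test_that("adding a facility point never lowers scores or the index", {
  set.seed(7)
  g <- grid_spec(n_rows = 15, n_cols = 15, cell_size = 50)
  layers <- lapply(facility_types(), function(ft) {
    facility_layer(ft, data.frame(x = runif(3, 0, 750), y = runif(3, 0, 750)))
  })
  names(layers) <- facility_types()
  before <- urban_quality_surface(g, layers)
  aug <- layers
  aug$pharmacies <- facility_layer(
    "pharmacies", rbind(layers$pharmacies$points,
                        data.frame(x = runif(1, 0, 750), y = runif(1, 0, 750)))
  )
  after <- urban_quality_surface(g, aug)
  expect_true(all(after$score$pharmacies$values >= before$score$pharmacies$values))
  expect_true(all(after$index$values >= before$index$values))
  expect_true(all(before$index$values >= 7 & before$index$values <= 21))
  expect_true(all(before$index$values == round(before$index$values)))
})

test_that("point extraction uses the half-open containing cell", {
  g <- grid_spec(n_rows = 1, n_cols = 2, cell_size = 50)
  idx <- raster_field(g, matrix(c(17, 18), 1, 2), kind = "index", n_layers = 6)
  expect_equal(extract_index_at_points(idx, data.frame(x = 25, y = 25)), 17)
  # x = 50 is the shared edge: belongs to the second cell's [50, 100) extent
  expect_equal(extract_index_at_points(idx, data.frame(x = 50, y = 25)), 18)
  expect_error(
    extract_index_at_points(idx, data.frame(x = 200, y = 25, id = "p9")),
    "outside grid extent.*p9"
  )
})

test_that("extraction agrees with direct per-point recomputation", {
  set.seed(11)
  g <- grid_spec(n_rows = 25, n_cols = 25, cell_size = 50)
  layers <- lapply(facility_types(), function(ft) {
    facility_layer(ft, data.frame(x = runif(4, 0, 1250), y = runif(4, 0, 1250)))
  })
  names(layers) <- facility_types()
  surf <- urban_quality_surface(g, layers)
  pts <- data.frame(x = runif(100, 0, 1250), y = runif(100, 0, 1250))
  got <- extract_index_at_points(surf$index, pts)
  # oracle: snap each point to its cell centre, then distance -> score -> sum
  cs <- g$cell_size
  cxy <- data.frame(x = (floor(pts$x / cs) + 0.5) * cs,
                    y = (floor(pts$y / cs) + 0.5) * cs)
  manual <- rowSums(sapply(layers, function(l) {
    classify_distance(oracle_nearest(cxy$x, cxy$y, l$points$x, l$points$y),
                      l$bands)
  }))
  expect_equal(got, manual)
})

test_that("quartile assignment matches ranks and handles degeneracy", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q), rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  expect_warning(qd <- assign_quartiles(rep(5, 10)), "degenerate")
  expect_true(all(qd == "Q1"))
  expect_error(assign_quartiles(1:3), "at least 4")
})

test_that("cohort quartiles are as balanced as integer ties allow", {
  co <- simulate_study(seed = 3)$cohort
  q <- assign_quartiles(co$index)
  edges <- attr(q, "edges")
  n <- length(co$index)
  counts <- cumsum(table(q)[c("Q1", "Q2", "Q3")])
  for (k in 1:3) {
    tie_group <- sum(co$index == edges[k])
    # right-closed binning can overshoot k*n/4 by at most the tie group
    # sharing the edge value, and never undershoots
    expect_gte(counts[[k]], k * n / 4 - 1)
    expect_lt(counts[[k]], k * n / 4 + tie_group + 1)
  }
  # on the rank scale (ties split evenly) the quarters are exact
  ranks <- rank(co$index, ties.method = "average")
  for (lev in levels(q)) {
    expect_gt(sum(q == lev), 0)
  }
})

test_that("distance_to_nearest matches geometry and the pairwise oracle", {
  lay <- facility_layer("pharmacies", data.frame(x = c(3, 10), y = c(4, 0)))
  expect_equal(distance_to_nearest(data.frame(x = 0, y = 0), lay), 5)
  expect_equal(distance_to_nearest(data.frame(x = 3, y = 4), lay), 0)
  set.seed(5)
  pts <- data.frame(x = runif(50, 0, 100), y = runif(50, 0, 100))
  fac <- data.frame(x = runif(10, 0, 100), y = runif(10, 0, 100))
  lay2 <- facility_layer("squares_parks", fac)
  expect_equal(distance_to_nearest(pts, lay2),
               oracle_nearest(pts$x, pts$y, fac$x, fac$y))
})
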