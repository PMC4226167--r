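test_that("points map to half-open voxels and out-of-bounds points error", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(10, 10, 20))
  expect_identical(pointToVoxel(c(1, 1, 1), g), c(0L, 0L, 0L))
  expect_identical(pointToVoxel(c(50, 0, 0), g), c(1L, 0L, 0L))
  expect_identical(pointToVoxel(c(499.999, 499.999, 999.999), g),
                   c(9L, 9L, 19L))
  expect_error(pointToVoxel(c(-1, 0, 0), g), "outside the grid")
  expect_error(pointToVoxel(c(500, 0, 0), g), "outside the grid")
})

test_that("every in-bounds point lies in exactly one voxel and volumes add up", {
  g <- VoxelGrid(c(-100, 0, 50), 50, c(4, 3, 5))
  b <- gridBounds(g)
  set.seed(11)
  p <- cbind(runif(500, b$lower[1], b$upper[1] - 1e-9),
             runif(500, b$lower[2], b$upper[2] - 1e-9),
             runif(500, b$lower[3], b$upper[3] - 1e-9))
  ijk <- pointToVoxel(p, g)
  lo <- sweep(ijk * g@spacing, 2, g@origin, `+`)
  expect_true(all(p >= lo & p < lo + g@spacing))
  expect_equal(nVoxels(g) * g@spacing^3, prod(b$upper - b$lower))
})

test_that("nearestColumn matches exhaustive search and flags septum points", {
  fr <- testFrame(tilt = TRUE)
  cl <- fr@columns
  # independent oracle: point-to-segment distance per column, loop form
  oracleNearest <- function(p) {
    d <- vapply(seq_len(nrow(cl)), function(ci) {
      ctr <- unlist(cl[ci, c("cx", "cy", "cz")])
      ax <- unlist(cl[ci, c("ax", "ay", "az")])
      half <- (cl$bottom_depth[ci] - cl$top_depth[ci]) / 2
      t <- sum((p - ctr) * ax)
      tc <- min(max(t, -half), half)
      sqrt(sum((p - (ctr + tc * ax))^2))
    }, numeric(1))
    cl$id[order(d, cl$id)[1]]
  }
  set.seed(4)
  for (r in 1:200) {
    p <- c(runif(1, 0, 500), runif(1, 0, 300), runif(1, 0, 450))
    expect_identical(nearestColumn(p, fr)$id, oracleNearest(p))
  }
  # column center is inside; ties break to the smallest id
  expect_identical(nearestColumn(c(150, 150, 225), fr),
                   list(id = "A", inside = TRUE))
  frS <- testFrame(tilt = FALSE)
  expect_identical(nearestColumn(c(250, 150, 225), frS)$id, "A")
  # radial distance 1.5 * radius (away from column B) -> same column, septum
  nc <- nearestColumn(c(150 - 1.5 * 75, 150, 225), frS)
  expect_identical(nc$id, "A")
  expect_false(nc$inside)
})

test_that("localAxis interpolates column axes and always returns unit vectors", {
  fr <- testFrame(tilt = TRUE)
  u <- c(0, 0, 1)
  v <- c(0.2, 0, 1) / sqrt(1.04)
  # on column A's axis: exactly A's axis
  expect_equal(localAxis(c(150, 150, 100), fr), u, tolerance = 1e-12)
  # symmetric-tilt frame: a point equidistant from both axes gets the
  # equal-weight mean of the two axes, renormalized
  uS <- c(-0.2, 0, 1) / sqrt(1.04)
  vS <- c(0.2, 0, 1) / sqrt(1.04)
  colsS <- fr@columns
  colsS[1, c("ax", "ay", "az")] <- uS
  colsS[2, c("ax", "ay", "az")] <- vS
  frS <- ReferenceFrame(fr@grid, colsS, fr@zones)
  expect_equal(localAxis(c(250, 150, 225), frS),
               (uS + vS) / 2 / sqrt(sum(((uS + vS) / 2)^2)),
               tolerance = 1e-9)
  # brute-force inverse-distance oracle on the tilted frame
  cl <- fr@columns
  segDist <- function(p, ci) {
    ctr <- unlist(cl[ci, c("cx", "cy", "cz")])
    ax <- unlist(cl[ci, c("ax", "ay", "az")])
    half <- (cl$bottom_depth[ci] - cl$top_depth[ci]) / 2
    t <- min(max(sum((p - ctr) * ax), -half), half)
    sqrt(sum((p - (ctr + t * ax))^2))
  }
  set.seed(8)
  for (r in 1:50) {
    p <- c(runif(1, 1, 499), runif(1, 1, 299), runif(1, 1, 449))
    w <- 1 / c(segDist(p, 1), segDist(p, 2))
    ex <- (w[1] * u + w[2] * v) / sum(w)
    ex <- ex / sqrt(sum(ex^2))
    expect_equal(localAxis(p, fr), ex, tolerance = 1e-9)
    expect_equal(sqrt(sum(localAxis(p, fr)^2)), 1, tolerance = 1e-9)
  }
  # a single-column frame returns that column's axis everywhere
  fr1 <- ReferenceFrame(fr@grid, fr@columns[2, ],
                        fr@zones[fr@zones$column_id == "B", ])
  expect_equal(localAxis(c(30, 30, 30), fr1), v, tolerance = 1e-9)
})

test_that("laminar zones follow the half-open depth convention", {
  fr <- testFrame(zoneMax = 400)
  # depth 0: most superficial zone
  expect_identical(laminarZoneOf(c(150, 150, 0), fr), "supragranular")
  # zone boundary depth belongs to the deeper zone
  expect_identical(laminarZoneOf(c(150, 150, 150), fr), "granular")
  expect_identical(laminarZoneOf(c(150, 150, 249.99), fr), "granular")
  # below the deepest zone: sentinel
  expect_identical(laminarZoneOf(c(150, 150, 425), fr), "outside")
})

test_that("frame construction validates geometry", {
  g <- VoxelGrid(c(0, 0, 0), 50, c(10, 6, 9))
  cols <- data.frame(id = "A", cx = 150, cy = 150, cz = 225,
                     ax = 0, ay = 0, az = 2, radius = 75,
                     top_depth = 0, bottom_depth = 450)
  zn <- data.frame(column_id = "A", zone = "z", depth_min = 0,
                   depth_max = 450)
  expect_error(ReferenceFrame(g, cols, zn), "unit")
  cols$az <- 1
  cols$top_depth <- 500
  expect_error(ReferenceFrame(g, cols, zn), "top_depth")
  zn2 <- data.frame(column_id = "A", zone = c("a", "b"),
                    depth_min = c(0, 100), depth_max = c(150, 300))
  cols$top_depth <- 0
  expect_error(ReferenceFrame(g, cols, zn2), "disjoint")
})
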