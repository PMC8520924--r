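test_that("shape metrics recover circle and square identities", {
  disk <- raster_disk(100)
  m <- shape_metrics(disk)
  expect_equal(m$circularity, 1, tolerance = 0.02)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(m$area, pi * 100^2, tolerance = 0.01)
  sq <- shape_metrics(raster_square(200))
  expect_equal(sq$circularity, pi / 4, tolerance = 0.04)
  expect_equal(sq$aspect_ratio, 1, tolerance = 0.02)
})

test_that("equivalent-ellipse AR and orientation match generator truth", {
  g <- gen_ellipse_masks(n = 1, ar_range = c(4, 4), mu = 30, kappa = 1e8,
                         size_range = c(50, 50), seed = 2)
  m <- shape_metrics(g$mask)
  expect_equal(m$aspect_ratio, 4, tolerance = 0.05 / 4)
  expect_equal(m$orientation, 30, tolerance = 1)
})

test_that("metrics are rotation-robust and exactly scale-equivariant", {
  g0 <- gen_ellipse_masks(1, c(3, 3), mu = 0, kappa = 1e8,
                          size_range = c(55, 55), seed = 4)
  g37 <- gen_ellipse_masks(1, c(3, 3), mu = 37, kappa = 1e8,
                           size_range = c(55, 55), seed = 4)
  m0 <- shape_metrics(g0$mask); m37 <- shape_metrics(g37$mask)
  expect_lt(abs(m37$area - m0$area) / m0$area, 0.02)
  expect_lt(abs(m37$aspect_ratio - m0$aspect_ratio) / m0$aspect_ratio, 0.02)
  m2 <- shape_metrics(g0$mask, pixel_size = 2)
  expect_equal(m2$area, 4 * m0$area)
  expect_equal(m2$perimeter, 2 * m0$perimeter)
  expect_equal(m2$aspect_ratio, m0$aspect_ratio)
})

test_that("AR estimates regress on truth with unit slope over AR 1-10", {
  g <- gen_ellipse_masks(n = 200, ar_range = c(1, 10), kappa = 0,
                         size_range = c(30, 40), seed = 7)
  m <- merge(shape_metrics(g$mask), g$truth$truth, by = "label")
  expect_equal(nrow(m), 200)
  slope <- stats::coef(stats::lm(aspect_ratio ~ ar, data = m))[2]
  expect_equal(unname(slope), 1, tolerance = 0.02)
})

test_that("empty and degenerate masks are handled", {
  expect_warning(m <- shape_metrics(matrix(0, 20, 20)), "no component")
  expect_equal(nrow(m), 0)
})

test_that("orientation histogram: counts, axial statistics, null and recovery", {
  oh <- orientation_histogram(c(10, 10, 10), n_bins = 6)
  expect_equal(sum(oh$counts), 3)
  expect_equal(oh$resultant_length, 1, tolerance = 1e-12)
  expect_equal(oh$circular_mean, 10, tolerance = 1e-9)
  expect_error(orientation_histogram(1:10, n_bins = 2), "n_bins")
  expect_warning(orientation_histogram(c(0, 95)), "wrapped")
  # uniform null: resultant length small at n = 1000
  set.seed(11)
  a <- rvonmises(1000, 0, 0) * 90 / pi
  expect_lt(orientation_histogram(a)$resultant_length, 0.08)
  # concentrated axial sample recovers the mean direction
  set.seed(12)
  ax <- rvonmises(500, 0, 8) / 2 * 180 / pi
  expect_lt(abs(orientation_histogram(ax)$circular_mean), 3)
})

test_that("sprout quantification recovers distances and excludes single cells", {
  sf <- gen_sprout_field(n_sprouts = 3, distance_range = c(120, 350),
                         single_cell_fraction = 1, seed = 5)
  sp <- sprout_quantification(sf$mask)
  expect_equal(sort(sp$distances), sort(sf$truth$truth$distance_px),
               tolerance = 1e-9)
  expect_equal(sp$max_distance, max(sf$truth$truth$distance_px))
  expect_equal(sp$n_single_cells, sf$truth$truth$n_single_cells)
  expect_equal(sp$n_sprouts, 3L)
  # scale equivariance of distances
  sp2 <- sprout_quantification(sf$mask, pixel_size = 1.3)
  expect_equal(sp2$distances, sp$distances * 1.3)
  # empty gel region
  sp0 <- sprout_quantification(matrix(0, 50, 50))
  expect_equal(sp0$max_distance, 0)
  expect_equal(sp0$n_sprouts, 0L)
  expect_error(sprout_quantification(sf$mask, interface_col = 10000),
               "outside")
})

test_that("strong directional bias puts the sprout polar mode in the +x bin", {
  sf <- gen_sprout_field(n_sprouts = 12, kappa = 50,
                         distance_range = c(100, 200), seed = 9)
  sp <- sprout_quantification(sf$mask)
  oh <- orientation_histogram(sp$direction_angles, n_bins = 8,
                              range_mode = "full-circle")
  mode_bin <- which.max(oh$counts)
  centers <- (utils::head(oh$breaks, -1) + utils::tail(oh$breaks, -1)) / 2
  expect_lt(abs(centers[mode_bin]), 45)
})
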