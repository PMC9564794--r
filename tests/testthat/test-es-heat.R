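test_that("cooling capacity combines shade, ETI and albedo as weighted", {
  spec <- grid_spec(1, 2)
  # forest pixel (shade 1, Kc 1, albedo 0.2) with ET0 at half the grid max:
  # ETI = 0.5 and CC = 0.6 + 0.2*0.5 + 0.2*0.2 = 0.74
  lulc <- es_raster(matrix(c(2, 2), 1, 2), spec)
  et0 <- es_raster(matrix(c(500, 1000), 1, 2), spec)
  hm <- heat_supply(lulc, et0, heat_params(dcool = 1))  # kernel ~ self only
  expect_equal(hm$values[1, 1], 0.74, tolerance = 1e-12)
  expect_equal(hm$values[1, 2], 0.6 + 0.2 + 0.04, tolerance = 1e-12)

  expect_error(heat_supply(lulc, es_raster(matrix(0, 1, 2), spec)),
               "ET0")
})

test_that("green-space cooling spreads by the distance-decay kernel", {
  # 7x7 all built-up except a centre green (forest) pixel
  spec <- grid_spec(7, 7)
  lu <- matrix(5, 7, 7); lu[4, 4] <- 2
  lulc <- es_raster(lu, spec)
  et0 <- es_raster(matrix(1000, 7, 7), spec)
  p <- heat_params(dcool = 100, large_green_area = 1e9)
  hm <- heat_supply(lulc, et0, p)
  # per-pixel CC values
  cc <- matrix(0.6 * 0 + 0.2 * 0.3 + 0.2 * 0.15, 7, 7)  # built-up
  cc[4, 4] <- 0.6 + 0.2 + 0.04                           # forest
  g <- matrix(0, 7, 7); g[4, 4] <- 1
  for (px in list(c(4, 5), c(2, 4), c(4, 4))) {
    expected_park <- ref_ccpark(cc, g, 30, 100, px[1], px[2])
    expected <- if (is.na(expected_park) || cc[px[1], px[2]] >= expected_park)
      cc[px[1], px[2]] else expected_park
    expect_equal(hm$values[px[1], px[2]], expected, tolerance = 1e-10)
  }
  # within dcool of the green pixel, sealed pixels inherit its cooling
  expect_gt(hm$values[4, 5], cc[4, 5])
  # pixels farther than dcool from any green keep their own CC
  expect_equal(hm$values[1, 1], cc[1, 1], tolerance = 1e-12)
  expect_true(all(hm$values >= 0 & hm$values <= 1))
})

test_that("membership in a large green patch preserves own cooling capacity", {
  spec <- grid_spec(8, 8)
  lu <- matrix(5, 8, 8)
  lu[1:3, 1:3] <- 3          # 9-pixel grassland patch = 8100 m2 (large)
  lu[1:2, 5:6] <- 2          # 4-pixel forest patch = 3600 m2 (not large)
  lu[8, 8] <- 3              # isolated single grass pixel
  lulc <- es_raster(lu, spec)
  et0 <- es_raster(matrix(1000, 8, 8), spec)
  cc_grass <- 0.2 * 0.65 + 0.2 * 0.2
  p <- heat_params(dcool = 300, large_green_area = 8100)
  hm <- heat_supply(lulc, et0, p)
  # grass inside the large patch keeps its own (low) CC even though nearby
  # forest raises the park value above it
  expect_equal(hm$values[2, 2], cc_grass, tolerance = 1e-12)
  # the isolated grass pixel is below the area threshold and takes the
  # distance-weighted park cooling, which the forest pulls above its own CC
  expect_gt(hm$values[8, 8], cc_grass)
  expect_true(all(hm$values >= 0 & hm$values <= 1))
})

test_that("heat demand is the normalized warm excess over the cropland mean", {
  spec <- grid_spec(1, 4)
  lulc <- es_raster(matrix(c(1, 1, 5, 5), 1, 4), spec)
  # cropland mean = 25; excesses 0, 0, 5, 10 -> normalized 0, 0, 0.5, 1
  lst <- es_raster(matrix(c(24, 26, 30, 35), 1, 4), spec)
  d <- heat_demand(lst, lulc)
  expect_equal(d$values[1, ], c(0, 0.1 / 1, 0.5, 1), tolerance = 1e-12)

  # exactly at the reference -> zero raw demand
  lst2 <- es_raster(matrix(c(25, 25, 25, 35), 1, 4), spec)
  d2 <- heat_demand(lst2, lulc)
  expect_equal(d2$values[1, 1:3], rep(0, 3))

  # every pixel at or below the reference: intended mode -> flat zero
  lst3 <- es_raster(matrix(c(22, 22, 19, 18), 1, 4), spec)
  expect_warning(d3 <- heat_demand(lst3, lulc), "constant")
  expect_true(all(d3$values == 0))

  # printed mode keeps the literal piecewise branch directions
  d4 <- heat_demand(lst, lulc, mode = "printed")
  expect_equal(which.max(d4$values), which.max(c(24, 26, 30, 35) >= 25))
  expect_error(heat_demand(lst, es_raster(matrix(5, 1, 4), spec)),
               "cultivated")
})
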