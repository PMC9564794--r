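test_that("curve-number supply reproduces hand-evaluated and limiting cases", {
  spec <- grid_spec(1, 4)
  # cultivated/A (CN 54), built-up/A (CN 85), water (CN 0), unused/D (CN 94)
  lulc <- es_raster(matrix(c(1, 5, 4, 6), 1, 4), spec)
  hsg <- es_raster(matrix(c(1, 1, 2, 4), 1, 4), spec)
  fm <- flood_supply(lulc, hsg, flood_params(design_storm = 100))
  # CN = 85: I = 25400/85 - 254, Rp = (100 - 0.2 I)^2 / (100 + 0.8 I)
  I <- 25400 / 85 - 254
  rp <- (100 - 0.2 * I)^2 / (100 + 0.8 * I)
  expect_equal(I, 44.8235, tolerance = 1e-4)
  expect_equal(rp, 61.0, tolerance = 1e-3)
  expect_equal(fm$values[1, 2], 1 - rp / 100, tolerance = 1e-12)
  expect_equal(fm$values[1, 2], 0.390, tolerance = 1e-3)
  expect_equal(fm$values[1, 3], 1)          # CN = 0: infinite retention

  # CN = 100 converts all rainfall to runoff
  p100 <- flood_params(design_storm = 100,
                       cn_table = matrix(100, 6, 4,
                                         dimnames = list(as.character(1:6),
                                                         c("A", "B", "C", "D"))))
  expect_equal(flood_supply(lulc, hsg, p100)$values[1, 1], 0)

  # small storms below the initial abstraction produce no runoff at all
  small <- flood_supply(lulc, hsg, flood_params(design_storm = 20))
  expect_equal(small$values[1, 1], 1)       # CN 54: 0.2 I = 43.3 mm > 20 mm

  # FM is nonincreasing in CN, and strictly decreasing once the storm
  # exceeds the initial abstraction (0.2 I)
  cns <- seq(5, 100, by = 5)
  fms <- sapply(cns, function(cn) {
    tab <- matrix(cn, 6, 4, dimnames = list(as.character(1:6),
                                            c("A", "B", "C", "D")))
    flood_supply(lulc, hsg, flood_params(design_storm = 150,
                                         cn_table = tab))$values[1, 1]
  })
  expect_true(all(diff(fms) <= 0))
  runoff_on <- 150 > 0.2 * (25400 / cns - 254)
  expect_true(all(diff(fms[runoff_on]) < 0))
})

test_that("flood demand combines normalized vulnerability indices", {
  spec <- grid_spec(2, 3)
  lulc <- es_raster(matrix(c(5, 5, 5, 2, 1, 3), 2, 3), spec)
  isa <- es_raster(matrix(c(0.9, 0.6, 0.3, 0, 0.05, 0.02), 2, 3), spec)
  # developed-density classes and per-LULC scores
  sc <- economic_score(lulc$values, isa$values, flood_params())
  expect_equal(sc[1, 1], 8)                 # a_ISA 0.9 -> high density
  expect_equal(sc[2, 1], 7)                 # 0.6 -> moderate
  expect_equal(sc[1, 2], 6)                 # 0.3 -> low
  expect_equal(sc[2, 2], 1)                 # forest
  expect_equal(sc[1, 3], 3)                 # cultivated
  expect_equal(sc[2, 3], 2)                 # grassland

  pop <- es_raster(matrix(c(9, 5, 4, 1, 2, 0), 2, 3), spec)
  old <- es_raster(matrix(c(2, 1, 1, 0.2, 0.3, 0), 2, 3), spec)
  kid <- es_raster(matrix(c(1, 0.6, 0.5, 0.1, 0.2, 0), 2, 3), spec)
  d <- flood_demand(pop, old, kid, isa, lulc, flood_params())
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_equal(max(d$values), 1)
  expect_equal(min(d$values), 0)
  # densest, most populated pixel carries the peak demand
  expect_equal(which.max(d$values), 1L)

  # spatially constant inputs degenerate to zero with a warning
  one <- es_raster(matrix(1, 2, 3), spec)
  luc <- es_raster(matrix(1, 2, 3), spec)
  warns <- capture_warnings(
    dc <- flood_demand(one, one, one, es_raster(matrix(0.5, 2, 3), spec),
                       luc))
  expect_true(any(grepl("constant", warns)))
  expect_true(all(dc$values == 0))
})
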