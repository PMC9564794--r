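test_that("ASCII grid round-trip preserves values, nodata mask and geometry", {
  set.seed(5)
  spec <- grid_spec(7, 5, cell_size = 30, origin_x = 1200, origin_y = 4000)
  v <- matrix(rnorm(35), 7, 5)
  v[c(3, 11, 30)] <- NA
  layer <- es_raster(v, spec, units = "mm")
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(layer, path)
  back <- read_ascii_grid(path, expected_spec = spec, units = "mm")
  expect_identical(is.na(back$values), is.na(v))
  expect_equal(back$values, v, tolerance = 1e-15)
  expect_equal(back$spec, spec, ignore_attr = TRUE)
  expect_equal(back$units, "mm")

  # all-nodata layer round-trips
  empty <- es_raster(matrix(NA_real_, 7, 5), spec)
  write_ascii_grid(empty, path)
  expect_true(all(is.na(read_ascii_grid(path)$values)))

  # grid mismatch names an alignment problem; unreadable file errors
  wrong <- grid_spec(7, 5, cell_size = 10)
  expect_error(read_ascii_grid(path, expected_spec = wrong), "alignment")
  expect_error(read_ascii_grid(file.path(tempdir(), "nope.asc")),
               "no such file")
})

test_that("landscape stack round-trips layers, units and tables", {
  gen <- small_landscape()
  dir <- withr::local_tempdir()
  write_landscape_stack(gen$stack, dir)
  back <- read_landscape_stack(dir)
  expect_setequal(names(back$layers), names(gen$stack$layers))
  expect_equal(back$layers$precip$values, gen$stack$layers$precip$values,
               tolerance = 1e-14)
  expect_equal(back$layers$precip$units, "mm")
  expect_equal(back$tables$water_use$agricultural,
               gen$stack$tables$water_use$agricultural, tolerance = 1e-12)
})

test_that("rasterization assigns by pixel center with the ascending-id tie rule", {
  # 2x2 grid, 30 m cells, split by a vertical boundary at x = 30:
  # centers x = 15, 45 -> two zones of 2 pixels each
  spec <- grid_spec(2, 2)
  rect <- function(x0, y0, x1, y1)
    rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
  zones <- data.frame(level = c("county", "township", "township",
                                "village", "village"),
                      zone_id = c(1L, 1L, 2L, 1L, 2L),
                      parent_id = c(NA, 1L, 1L, 1L, 2L))
  polys <- list(
    county = list(`1` = rect(0, 0, 60, 60)),
    township = list(`1` = rect(0, 0, 30, 60), `2` = rect(30, 0, 60, 60)),
    village = list(`1` = rect(0, 0, 30, 60), `2` = rect(30, 0, 60, 60)))
  hier <- admin_hierarchy(zones, polys)
  zr <- rasterize_hierarchy(hier, spec)
  expect_equal(zr$township$values, matrix(c(1, 1, 2, 2), 2, 2))
  expect_equal(sum(zr$township$values == 1), 2)

  # center exactly on a shared edge goes to the lower zone_id:
  # boundary at x = 15 puts column-1 centers on the edge
  polys$township <- list(`1` = rect(0, 0, 15, 60), `2` = rect(15, 0, 60, 60))
  polys$village <- polys$township
  hier2 <- admin_hierarchy(zones, polys)
  zr2 <- rasterize_hierarchy(hier2, spec)
  expect_equal(zr2$township$values[, 1], c(1, 1))
  expect_equal(zr2$township$values[, 2], c(2, 2))
})

test_that("village zones grouped by parent reproduce the township raster", {
  gen <- small_landscape()
  pm <- parent_map(gen$hierarchy, "village")
  regrouped <- regroup_zones(gen$zones$village, pm)
  expect_equal(regrouped$values, gen$zones$township$values)
  pm2 <- parent_map(gen$hierarchy, "township")
  expect_equal(regroup_zones(gen$zones$township, pm2)$values,
               gen$zones$county$values)
})

test_that("hierarchy GeoJSON round-trips ids, parents and rings", {
  hier <- rect_hierarchy()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_hierarchy_geojson(hier, path)
  back <- read_hierarchy_geojson(path)
  expect_equal(back$zones[order(back$zones$level, back$zones$zone_id), ],
               hier$zones[order(hier$zones$level, hier$zones$zone_id), ],
               ignore_attr = TRUE)
  expect_equal(back$polygons$village[["3"]], hier$polygons$village[["3"]],
               ignore_attr = TRUE)
  # rasterizations of the two objects agree
  spec <- grid_spec(8, 8)
  expect_equal(rasterize_hierarchy(back, spec)$village$values,
               rasterize_hierarchy(hier, spec)$village$values)
})

test_that("co-registration is enforced and hierarchy invariants validated", {
  a <- make_raster(1, 2, 2)
  b <- es_raster(matrix(1, 2, 2), grid_spec(2, 2, cell_size = 10))
  expect_error(zonal_aggregate(a, b), "co-registered")
  zones <- data.frame(level = c("county", "township", "village"),
                      zone_id = 1L, parent_id = c(NA, 1L, 99L))
  r <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  polys <- list(county = list(`1` = r), township = list(`1` = r),
                village = list(`1` = r))
  expect_error(admin_hierarchy(zones, polys), "parent")
})
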