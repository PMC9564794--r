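test_that("generation is fully deterministic under a fixed seed", {
  cfg <- landscape_config(spec = grid_spec(50, 50), seed = 9,
                          n_counties = 2, townships_per_county = 2,
                          villages_per_township = 2)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  for (nm in names(a$stack$layers))
    expect_identical(a$stack$layers[[nm]]$values, b$stack$layers[[nm]]$values,
                     info = nm)
  expect_identical(a$stack$tables$water_use, b$stack$tables$water_use)
  expect_identical(a$hierarchy$polygons, b$hierarchy$polygons)
})

test_that("degenerate class weights yield a single-class landscape", {
  w <- c(cultivated = 0, forest = 0, grassland = 0, water = 1,
         builtup = 0, unused = 0)
  cfg <- landscape_config(spec = grid_spec(30, 30), seed = 2,
                          n_counties = 2, townships_per_county = 2,
                          villages_per_township = 2,
                          lulc_class_weights = w)
  gen <- generate_landscape(cfg)
  expect_true(all(gen$stack$layers$lulc$values == lulc_codes()[["water"]]))
})

test_that("realized LULC shares track configured weights within 5 points", {
  weights <- landscape_config()$lulc_class_weights
  worst <- 0
  for (seed in 1:10) {
    cfg <- landscape_config(spec = grid_spec(200, 200), seed = seed)
    lu <- generate_landscape(cfg)$stack$layers$lulc$values
    share <- tabulate(lu, nbins = 6) / length(lu)
    worst <- max(worst, abs(share - as.numeric(weights[order(lulc_codes())])))
  }
  expect_lt(worst, 0.05)
})

test_that("generated fields carry the configured spatial structure", {
  gen <- full_landscape()
  l <- gen$stack$layers
  nr <- nrow(l$pm25$values); nc <- ncol(l$pm25$values)
  nw <- l$pm25$values[1:(nr / 2), 1:(nc / 2)]
  se <- l$pm25$values[(nr / 2 + 1):nr, (nc / 2 + 1):nc]
  expect_gt(mean(nw), mean(se))          # pollution increases toward the NW
  # row/column band means decrease monotonically along the gradient
  band <- function(m, k) sapply(split(seq_len(nrow(m)),
                                      cut(seq_len(nrow(m)), k)),
                                function(i) mean(m[i, ]))
  expect_true(all(diff(band(l$pm25$values, 5)) < 0))

  expect_gt(cor(as.vector(l$lst$values), as.vector(l$impervious$values)),
            0.5)                          # LST-impervious coupling

  # population decays away from the urban cores
  core <- esbundles:::core_kernel(gen$stack$spec,
                                  landscape_config()$urban_core_centers)
  near <- core > stats::quantile(core, 0.9)
  far <- core < stats::quantile(core, 0.1)
  expect_gt(mean(l$population$values[near]), 5 * mean(l$population$values[far]))

  expect_true(all(l$hsg$values %in% 1:4))
  expect_true(all(abs(l$sand$values + l$silt$values + l$clay$values - 100)
                  < 1e-9))
  expect_true(all(l$precip$values > 0))
  expect_true(all(l$impervious$values >= 0 & l$impervious$values <= 1))

  # water-use totals only where the target class exists in the village
  wu <- gen$stack$tables$water_use
  zr <- gen$zones$village$values
  lu <- l$lulc$values
  for (i in seq_len(nrow(wu))) {
    if (wu$agricultural[i] > 0)
      expect_gt(sum(lu == 1 & zr == wu$zone_id[i], na.rm = TRUE), 0)
  }
})

test_that("a grid too small for the requested hierarchy is rejected", {
  cfg <- landscape_config(spec = grid_spec(5, 5), seed = 1,
                          n_counties = 2, townships_per_county = 2,
                          villages_per_township = 2)
  expect_error(generate_landscape(cfg), "too small")
})

test_that("the generated stack satisfies every quantification precondition", {
  gen <- small_landscape()
  expect_no_error(quantify_services(gen$stack, gen$zones$village))
})
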