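test_that("zonal aggregation handles constants, single pixels and nesting", {
  spec <- grid_spec(2, 4)
  r <- es_raster(matrix(c(7, 7, 7, 7, 7, 7, 7, 7), 2, 4), spec)
  zr <- es_raster(matrix(c(1, 1, 1, 2, 2, 2, 2, 3), 2, 4), spec)
  m <- zonal_aggregate(r, zr, "mean")
  expect_equal(m$value, c(7, 7, 7))                # constant -> constant
  expect_equal(m$n_pixels, c(3, 4, 1))             # incl. single-pixel zone
  vals <- es_raster(matrix(1:8, 2, 4), spec)
  s <- zonal_aggregate(vals, zr, "sum")
  expect_equal(s$value[3], 8)                      # the pixel's own value
  # all-nodata zone is an error
  vals$values[zr$values == 3] <- NA
  expect_error(zonal_aggregate(vals, zr, "sum"), "zone")
})

test_that("ESDR matches its definition and invariances", {
  expect_equal(esdr(c(2, 5), c(2, 5)), c(0, 0))    # S = D everywhere
  expect_equal(esdr(c(3, 1), c(1, 2))[1], 0.8)     # (3-1)/((3+2)/2)
  # invariant to common positive rescaling
  S <- runif(10, 0, 5); D <- runif(10, 0, 5)
  expect_equal(esdr(7.3 * S, 7.3 * D), esdr(S, D), tolerance = 1e-12)
  # bounded in [-2, 2] with sign(S - D), over many random draws
  set.seed(1)
  for (i in 1:200) {
    S <- runif(8, 0, 100); D <- runif(8, 0, 100)
    r <- esdr(S, D)
    expect_true(all(r >= -2 & r <= 2))
    expect_true(all(sign(r) == sign(S - D)))
  }
  expect_error(esdr(c(0, 0), c(0, 0)), "Smax")
})

test_that("min-max normalization is linear, order preserving and guarded", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- rnorm(50)
  n <- minmax_normalize(x)
  expect_equal(n[which.min(x)], 0)
  expect_equal(n[which.max(x)], 1)
  expect_equal(order(n), order(x))
  expect_equal(minmax_normalize(c(2, 4, 6), to = "symmetric"), c(-1, 0, 1))
  expect_error(minmax_normalize(rep(3, 5)), "constant")
})

test_that("budget tables aggregate per scale with nested additivity", {
  gen <- small_landscape()
  services <- quantify_services(gen$stack, gen$zones$village)
  budgets <- build_budget_tables(services, gen$zones, gen$hierarchy)
  expect_named(budgets, c("county", "township", "village"))
  agg <- attr(budgets$village, "aggregation")
  expect_equal(agg[["CP"]], "sum"); expect_equal(agg[["HM"]], "mean")

  # extensive services: county totals equal the sum of member townships,
  # and transitively of member villages
  pm_t <- parent_map(gen$hierarchy, "township")
  pm_v <- parent_map(gen$hierarchy, "village")
  for (svc in c("CP", "WR", "PR")) for (side in c("_S", "_D")) {
    col <- paste0(svc, side)
    by_t <- tapply(budgets$township[[col]],
                   pm_t[as.character(budgets$township$zone_id)], sum)
    expect_equal(as.numeric(by_t[as.character(budgets$county$zone_id)]),
                 budgets$county[[col]], tolerance = 1e-9, info = col)
    v_to_c <- pm_t[as.character(pm_v[as.character(budgets$village$zone_id)])]
    by_v <- tapply(budgets$village[[col]], v_to_c, sum)
    expect_equal(as.numeric(by_v[as.character(budgets$county$zone_id)]),
                 budgets$county[[col]], tolerance = 1e-9, info = col)
  }

  # ESDR columns respect the bound and the sign convention
  for (lv in names(budgets)) {
    m <- esdr_matrix(budgets[[lv]])
    expect_true(all(m >= -2 & m <= 2))
    for (svc in colnames(m)) {
      diff_sd <- budgets[[lv]][[paste0(svc, "_S")]] -
        budgets[[lv]][[paste0(svc, "_D")]]
      expect_true(all(sign(m[, svc]) == sign(diff_sd)))
    }
  }

  # a single-zone scale degenerates to (S - D) / ((S + D) / 2)
  one <- esdr(5, 3)
  expect_equal(one, (5 - 3) / ((5 + 3) / 2))
})

test_that("crop deficits concentrate where population is, on the cores", {
  gen <- full_landscape()
  services <- quantify_services(gen$stack, gen$zones$village)
  budgets <- build_budget_tables(services, gen$zones, gen$hierarchy)
  v <- budgets$village
  pop <- zonal_aggregate(gen$stack$layers$population, gen$zones$village,
                         "sum")
  stopifnot(all(pop$zone_id == v$zone_id))
  # the most populated villages run crop deficits; the least do not
  top <- order(pop$value, decreasing = TRUE)[1:5]
  bottom <- order(pop$value)[1:5]
  expect_true(all(v$CP_esdr[top] < 0))
  expect_gt(mean(v$CP_esdr[bottom]), mean(v$CP_esdr[top]))
})
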