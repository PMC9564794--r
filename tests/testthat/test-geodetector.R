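test_that("the q-statistic matches brute-force variance decomposition", {
  expect_equal(q_statistic(c(1, 2, 3, 4), c("A", "A", "B", "B")), 0.8)
  # y constant within strata, different across -> fully determined
  expect_equal(q_statistic(c(5, 5, 2, 2, 9), c(1, 1, 2, 2, 3)), 1)
  # one stratum for everything -> no explanation
  expect_equal(q_statistic(rnorm(20), rep("a", 20)), 0)
  # random small instances against the independent sum-of-squares oracle
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    y <- rnorm(n)
    strata <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    strata[1:2] <- c("a", "b")                  # ensure >= 2 strata
    expect_equal(q_statistic(y, strata), ref_q(y, strata),
                 tolerance = 1e-12)
  }
  expect_error(q_statistic(rep(2, 6), rep(1:2, 3)), "variance")
})

test_that("q is invariant to stratum relabelling and affine y transforms", {
  set.seed(3)
  y <- rnorm(40)
  strata <- sample(1:5, 40, replace = TRUE)
  q0 <- q_statistic(y, strata)
  expect_equal(q_statistic(y, 6 - strata), q0, tolerance = 1e-12)
  expect_equal(q_statistic(-2.5 * y + 7, strata), q0, tolerance = 1e-12)
})

test_that("quantile discretization is balanced, tie-aware and rank invariant", {
  s <- discretize(1:10, n_strata = 5)
  expect_equal(as.numeric(table(s)), rep(2, 5))
  expect_error(discretize(rep(1, 10)), "constant")
  x <- rlnorm(100)
  expect_equal(discretize(x, 4), discretize(log(x), 4))  # monotone transform
  expect_warning(s2 <- discretize(c(rep(0, 6), 1:6), 5), "merged")
  expect_true(all(table(s2) > 0))
  ei <- discretize(c(0, 1, 2, 3, 10), 2, method = "equal_interval")
  expect_equal(ei, c(1L, 1L, 1L, 1L, 2L))
})

test_that("permutation significance is seeded, bounded and sane", {
  set.seed(2)
  y <- c(rnorm(20, 0), rnorm(20, 4))
  strata <- rep(1:2, each = 20)
  p1 <- q_significance(y, strata, n_perm = 199, seed = 7)
  p2 <- q_significance(y, strata, n_perm = 199, seed = 7)
  expect_identical(p1, p2)
  # a perfectly determined response attains the smallest possible p
  expect_equal(q_significance(rep(c(0, 1), each = 10), rep(1:2, each = 10),
                              n_perm = 199, seed = 1), 1 / 200)
  expect_error(q_significance(y, strata, n_perm = 50), "99")
})

test_that("increasing planted effect size never decreases the median q", {
  effects <- c(0, 0.5, 1, 2)
  med <- sapply(effects, function(e) {
    qs <- sapply(1:30, function(rep) {
      set.seed(1000 + rep)
      labels <- sample(1:4, 60, replace = TRUE)
      driver <- e * labels + rnorm(60)
      q_statistic(as.numeric(labels), discretize(driver, 5))
    })
    median(qs)
  })
  expect_true(all(diff(med) >= 0))
  expect_lt(med[1], 0.15)                          # null effect stays small
})

test_that("factor detection ranks a planted dominant driver first", {
  planted <- plant_esdr_matrix(diag(6), n_zones = 64, noise_sd = 0.05,
                               seed = 21)
  bundles <- kmeans_bundles(planted$esdr, k = 6, seed = 2)
  set.seed(77)
  drivers <- data.frame(zone_id = as.integer(rownames(planted$esdr)))
  for (nm in c("GDP", "PRE", "TEM", "DEM")) drivers[[nm]] <- rnorm(64)
  drivers$POP <- as.numeric(planted$labels) + rnorm(64, sd = 0.2)
  qt <- factor_detection(bundles, drivers, n_perm = 199, seed = 5)
  expect_equal(qt$driver[1], "POP")
  expect_true(qt$significant[1])
  expect_true(all(qt$q >= 0 & qt$q <= 1))
  # the indicator-mean variant agrees on the ranking here
  qt2 <- factor_detection(bundles, drivers, n_perm = 199, seed = 5,
                          y_mode = "indicator-mean")
  expect_equal(qt2$driver[1], "POP")
  expect_error(factor_detection(bundles, drivers[1:10, ]), "align")
})
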