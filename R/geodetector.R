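#' Discretize a continuous driver into strata
#'
#' The factor detector needs a categorical X; continuous drivers are cut
#' into `n_strata` groups. Quantile cuts (default) give near-equal group
#' sizes and are invariant to monotone transforms of the driver; equal-
#' interval cuts split the value range evenly. Ties at a cut point fall to
#' the lower stratum. Duplicate cut points (heavily tied data) are merged
#' with a warning, so every returned stratum is nonempty.
#'
#' @param x Numeric driver values.
#' @param n_strata Number of strata (default 5).
#' @param method `"quantile"` (default) or `"equal_interval"`.
#' @return Integer stratum labels in 1..(number of nonempty strata).
#' @export
discretize <- function(x, n_strata = 5, method = c("quantile",
                                                   "equal_interval")) {
  method <- match.arg(method)
  if (length(unique(x)) < 2) stop("constant driver cannot be stratified")
  breaks <- if (method == "quantile") {
    stats::quantile(x, probs = seq(0, 1, length.out = n_strata + 1),
                    names = FALSE, type = 7)
  } else {
    seq(min(x), max(x), length.out = n_strata + 1)
  }
  if (anyDuplicated(breaks)) {
    warning("duplicate cut points; strata merged")
    breaks <- unique(breaks)
  }
  if (length(breaks) < 3) stop("too few distinct values to form 2 strata")
  lab <- cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  as.integer(lab)
}

#' Geodetector factor-detector q-statistic
#'
#' q = 1 - sum_h N_h sigma_h^2 / (N sigma^2), the share of the spatial
#' variance of y explained by the stratification. Population (biased)
#' variances are used throughout, which makes the decomposition exact:
#' q = 1 means y is fully determined by the strata, q = 0 means a single
#' stratum (no explanation). q is invariant to relabelling strata and to
#' affine transforms of y.
#'
#' @param y Numeric response per unit.
#' @param strata Stratum labels (any type coercible to factor), all strata
#'   nonempty.
#' @return q in [0, 1].
#' @export
q_statistic <- function(y, strata) {
  stopifnot(length(y) == length(strata))
  n <- length(y)
  v <- pop_var(y)
  if (v <= 0) stop("zero total variance: q undefined")
  f <- factor(strata)
  within <- sum(tapply(y, f, function(g) length(g) * pop_var(g)))
  q <- 1 - within / (n * v)
  min(max(q, 0), 1)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Permutation significance of the q-statistic
#'
#' The observed q is compared with q recomputed on `n_perm` random
#' permutations of y over the strata; p = (1 + #\{q_perm >= q_obs\}) /
#' (1 + n_perm). Assumption-free and exactly reproducible under a seed; the
#' smallest attainable p is 1 / (1 + n_perm).
#'
#' @param y Numeric response.
#' @param strata Stratum labels.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return p-value in (0, 1].
#' @export
q_significance <- function(y, strata, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  q_obs <- q_statistic(y, strata)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) q_statistic(sample(y), strata) >= q_obs,
               logical(1)))
  })
  (1 + exceed) / (1 + n_perm)
}

#' Per-zone driver table (zonal means of candidate driver layers)
#'
#' @param stack A `landscape_stack` holding the driver layers.
#' @param zone_raster Zone `es_raster` at the scale of interest.
#' @param drivers Character vector mapping driver names to stack layer
#'   names; default the 14 standard candidates.
#' @return Data frame: zone_id plus one column per driver (zonal means).
#' @export
driver_table <- function(stack, zone_raster, drivers = default_drivers()) {
  out <- NULL
  for (nm in names(drivers)) {
    agg <- zonal_aggregate(stack_layer(stack, drivers[[nm]]), zone_raster,
                           "mean")
    block <- data.frame(zone_id = agg$zone_id, v = agg$value)
    names(block)[2] <- nm
    out <- if (is.null(out)) block else merge(out, block, by = "zone_id")
  }
  out
}

#' @rdname driver_table
#' @export
default_drivers <- function() {
  c(GDP = "gdp", POP = "population", IS = "impervious", NIS = "nis",
    PRE = "precip", TEM = "temperature", WS = "wind", SR = "solar",
    SAND = "sand", SILT = "silt", CLAY = "clay", DEM = "dem",
    SLOPE = "slope", GR = "roughness")
}

#' Factor detection of bundle drivers at one scale
#'
#' For each driver: stratify its zonal means, then measure how much of the
#' bundle pattern the strata explain. Bundle labels are categorical; in the
#' default `y_mode = "label-code"` the integer label codes are used as y
#' (the common practice in applied factor-detector studies). The
#' `"indicator-mean"` mode computes q on each bundle's 0/1 membership
#' indicator and averages over bundles — the statistically defensible
#' variant — and is reported under its own mode tag.
#'
#' @param bundles A `bundle_result`.
#' @param drivers Output of [driver_table()] for the same zones.
#' @param n_strata Strata per driver (default 5).
#' @param n_perm Permutations for the significance test (default 999).
#' @param seed Integer seed.
#' @param y_mode `"label-code"` (default) or `"indicator-mean"`.
#' @param alpha Significance threshold for the flag column (default 0.1).
#' @return Data frame (one row per driver): driver, q, p_value, significant,
#'   n_strata, method, y_mode, ranked by descending q.
#' @export
factor_detection <- function(bundles, drivers, n_strata = 5, n_perm = 999,
                             seed = 1, y_mode = c("label-code",
                                                  "indicator-mean"),
                             alpha = 0.1) {
  y_mode <- match.arg(y_mode)
  ids <- as.character(drivers$zone_id)
  if (!setequal(ids, names(bundles$labels)))
    stop("driver table zones and bundle labels do not align")
  labels <- bundles$labels[ids]
  dnames <- setdiff(names(drivers), "zone_id")
  res <- lapply(seq_along(dnames), function(i) {
    nm <- dnames[i]
    strata <- discretize(drivers[[nm]], n_strata = n_strata)
    dseed <- (seed + 1000L * i) %% 2147483647L
    if (y_mode == "label-code") {
      y <- as.numeric(labels)
      q <- q_statistic(y, strata)
      p <- q_significance(y, strata, n_perm = n_perm, seed = dseed)
    } else {
      ks <- sort(unique(labels))
      qs <- ps <- numeric(length(ks))
      for (j in seq_along(ks)) {
        y <- as.numeric(labels == ks[j])
        qs[j] <- q_statistic(y, strata)
        ps[j] <- q_significance(y, strata, n_perm = n_perm,
                                seed = (dseed + j) %% 2147483647L)
      }
      q <- mean(qs); p <- min(ps)
    }
    data.frame(driver = nm, q = q, p_value = p, significant = p < alpha,
               n_strata = length(unique(strata)), method = "quantile",
               y_mode = y_mode)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$q), ]
  rownames(out) <- NULL
  out
}
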