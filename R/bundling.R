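#' Elbow selection of the cluster count
#'
#' Runs k-means (best of `n_restarts`) for each candidate k, records the
#' within-cluster sum of squares (WSS), and picks the k with the largest
#' perpendicular distance from the WSS curve to the chord joining its
#' endpoints. The curve is always returned for inspection; the pipeline does
#' not silently override a configured k.
#'
#' @param mat Numeric matrix (zones x services), normalized per column.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param n_restarts Random restarts per k (default 25).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `k` (selected), `wss_curve` (data frame k, wss).
#' @export
elbow_select <- function(mat, k_range = 2:10, n_restarts = 25, seed = 1) {
  mat <- as.matrix(mat)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(mat))
    stop("k_range exceeds the number of rows")
  if (nrow(unique(mat)) < 2) stop("degenerate input: all rows identical")
  wss <- with_seed(seed, vapply(k_range, function(k) {
    if (k == nrow(mat)) return(0)     # one point per cluster
    stats::kmeans(mat, centers = k, nstart = n_restarts,
                  iter.max = 100)$tot.withinss
  }, numeric(1)))
  k1 <- k_range[1]; k2 <- k_range[length(k_range)]
  w1 <- wss[1]; w2 <- wss[length(wss)]
  # perpendicular distance of (k, wss) to the chord (k1,w1)-(k2,w2)
  dist <- abs((w2 - w1) * (k_range - k1) - (k2 - k1) * (wss - w1)) /
    sqrt((w2 - w1)^2 + (k2 - k1)^2)
  list(k = k_range[which.max(dist)],
       wss_curve = data.frame(k = k_range, wss = wss))
}

#' K-means ES budget bundles
#'
#' Lloyd-style k-means (via `stats::kmeans`, best of `n_restarts` by total
#' WSS) on the normalized per-zone ESDR matrix. Labels are renumbered 1..k
#' by descending bundle area share so the numbering is reproducible; results
#' are deterministic for a fixed seed.
#'
#' @param mat Numeric matrix (zones x services), each column min-max
#'   normalized; zone ids as row names.
#' @param k Number of bundles (default 6).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 25).
#' @param zone_areas Optional per-zone areas (m2) for the area shares;
#'   default equal areas.
#' @return Object of class `bundle_result`: labels (named by zone),
#'   centroids (k x services), zscore_profiles, area_share, wss, k, seed.
#' @export
kmeans_bundles <- function(mat, k = 6, seed = 1, n_restarts = 25,
                           zone_areas = NULL) {
  mat <- as.matrix(mat)
  if (k > nrow(unique(mat)))
    stop("k exceeds the number of distinct rows")
  if (is.null(zone_areas)) zone_areas <- rep(1, nrow(mat))
  fit <- if (k == nrow(mat)) {
    # one zone per bundle: the exact zero-WSS solution
    list(cluster = seq_len(k), centers = mat, tot.withinss = 0)
  } else {
    with_seed(seed, stats::kmeans(mat, centers = k, nstart = n_restarts,
                                  iter.max = 100))
  }
  share <- tapply(zone_areas, factor(fit$cluster, levels = 1:k), sum)
  share[is.na(share)] <- 0
  share <- share / sum(zone_areas)
  ord <- order(share, decreasing = TRUE)        # old label -> rank
  relabel <- integer(k); relabel[ord] <- 1:k
  labels <- relabel[fit$cluster]
  names(labels) <- rownames(mat)
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- 1:k
  structure(list(k = k, labels = labels, centroids = centroids,
                 area_share = as.numeric(share[ord]),
                 zscore_profiles = zscore_profiles(mat, labels),
                 wss = fit$tot.withinss, seed = seed,
                 n_restarts = n_restarts),
            class = "bundle_result")
}

#' @export
print.bundle_result <- function(x, ...) {
  cat(sprintf("<bundle_result> k = %d, %d zones, WSS = %.4g\n",
              x$k, length(x$labels), x$wss))
  cat("area shares:", paste(sprintf("%.1f%%", 100 * x$area_share),
                            collapse = " "), "\n")
  invisible(x)
}

#' Z-score bundle profiles
#'
#' For each service the bundle means are standardized across bundles:
#' (mean_b - mean of bundle means) / sd of bundle means. Zero marks the
#' average bundle; positive values mark bundles above the cross-bundle
#' average for that service. A service whose bundle means are all equal is
#' degenerate and profiles to 0.
#'
#' @param mat Numeric matrix (zones x services).
#' @param labels Integer bundle labels (length nrow(mat)).
#' @return k x services numeric matrix.
#' @export
zscore_profiles <- function(mat, labels) {
  mat <- as.matrix(mat)
  k <- length(unique(labels))
  if (k < 2) stop("z-score profiles need at least two bundles")
  means <- apply(mat, 2, function(col) tapply(col, labels, mean))
  apply(means, 2, function(m) {
    s <- stats::sd(m)
    if (!is.finite(s) || s == 0) rep(0, length(m)) else (m - mean(m)) / s
  })
}

#' Bundle the zones of one budget table
#'
#' Min-max normalizes each service's ESDR column, runs [kmeans_bundles()],
#' and attaches elbow diagnostics over `k_range`.
#'
#' @param budget_table One element of [build_budget_tables()] output.
#' @param k Number of bundles (default 6).
#' @param seed,n_restarts Passed to [kmeans_bundles()].
#' @param k_range Candidate counts for the elbow diagnostics.
#' @param zone_areas Optional per-zone areas (m2).
#' @return A `bundle_result` with an `elbow` element.
#' @export
bundle_zones <- function(budget_table, k = 6, seed = 1, n_restarts = 25,
                         k_range = 2:10, zone_areas = NULL) {
  m <- esdr_matrix(budget_table)
  norm <- apply(m, 2, minmax_normalize)
  rownames(norm) <- rownames(m)
  res <- kmeans_bundles(norm, k = k, seed = seed, n_restarts = n_restarts,
                        zone_areas = zone_areas)
  res$elbow <- elbow_select(norm, k_range = k_range[k_range <= nrow(norm)],
                            n_restarts = n_restarts, seed = seed)
  res$scale <- attr(budget_table, "scale")
  res
}
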