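#' Heat-mitigation supply: cooling capacity with green-space distance decay
#'
#' Per-pixel cooling capacity CC = 0.6*shade + 0.2*ETI + 0.2*albedo with
#' ETI = Kc * ET0 / ETmax clipped to [0, 1]. Each pixel also receives the
#' cooling of nearby green space: CCpark is the weighted mean of CC over
#' green pixels (g = 1) within `dcool`, weights exp(-d / dcool) normalized to
#' sum 1. A pixel keeps its own CC when it belongs to a connected green patch
#' (4-neighbour adjacency) of at least `large_green_area` m2, or when
#' CC >= CCpark, or when no green pixel lies within `dcool`; otherwise it
#' takes CCpark. All outputs lie in [0, 1].
#'
#' @param lulc LULC `es_raster`.
#' @param et0 Potential-evapotranspiration `es_raster`, mm.
#' @param params A [heat_params()].
#' @return Supply `es_raster` in [0, 1].
#' @export
heat_supply <- function(lulc, et0, params = heat_params()) {
  check_coregistered(lulc, et0)
  lu <- lulc$values
  idx <- match(lu, params$coef$lucode)
  if (any(is.na(idx) & !is.na(lu)))
    stop("LULC code missing from the heat coefficient table")
  etmax <- suppressWarnings(max(et0$values, na.rm = TRUE))
  if (!is.finite(etmax) || etmax <= 0) stop("maximum ET0 over the grid is 0")
  eti <- pmin(pmax(matrix(params$coef$kc[idx], nrow(lu), ncol(lu)) *
                     et0$values / etmax, 0), 1)
  wts <- params$weights
  cc <- wts[["shade"]] * matrix(params$coef$shade[idx], nrow(lu), ncol(lu)) +
    wts[["eti"]] * eti +
    wts[["albedo"]] * matrix(params$coef$albedo[idx], nrow(lu), ncol(lu))
  g <- matrix(as.numeric(params$coef$g[idx] == 1L), nrow(lu), ncol(lu))
  nodata <- is.na(lu) | is.na(cc)
  cc0 <- cc; cc0[nodata] <- 0
  g0 <- g; g0[nodata] <- 0

  cell <- lulc$spec$cell_size
  kern <- decay_kernel(params$dcool, cell)
  den <- conv2_same(g0, kern)
  num <- conv2_same(cc0 * g0, kern)
  ccpark <- ifelse(den > 1e-12, num / den, NA_real_)

  patch <- EBImage::bwlabel(g0)
  sizes <- tabulate(patch[patch > 0])
  min_px <- params$large_green_area / cell_area(lulc$spec)
  in_large <- patch > 0 & sizes[pmax(patch, 1)] >= min_px

  hm <- ifelse(in_large | is.na(ccpark) | cc >= ccpark, cc, ccpark)
  hm[nodata] <- NA_real_
  wrap_raster(hm, lulc, units = "1")
}

# Distance-decay kernel exp(-d/dcool), truncated at d <= dcool.
decay_kernel <- function(dcool, cell) {
  r <- floor(dcool / cell)
  off <- (-r):r
  d <- cell * sqrt(outer(off^2, off^2, `+`))
  k <- exp(-d / dcool)
  k[d > dcool] <- 0
  k
}

# Zero-padded FFT convolution returning the "same"-size central block.
conv2_same <- function(a, k) {
  na_r <- nrow(a); na_c <- ncol(a)
  kr <- nrow(k); kc <- ncol(k)
  nr <- na_r + kr - 1L; nc <- na_c + kc - 1L
  pa <- matrix(0, nr, nc); pa[1:na_r, 1:na_c] <- a
  pk <- matrix(0, nr, nc); pk[1:kr, 1:kc] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    (nr * nc)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[(r0 + 1L):(r0 + na_r), (c0 + 1L):(c0 + na_c)]
}

#' Heat-mitigation demand: urban-heat-island intensity over cropland
#'
#' The reference temperature is the mean land-surface temperature over
#' cultivated pixels. In the default `"intended"` mode the raw demand is
#' max(0, Ti - Tref) — the UHI excess; the `"printed"` mode keeps the
#' literal piecewise form (Ti - Tref where Ti < Tref, else 0) for fidelity
#' with the source formulation. The raw field is then min-max normalized to
#' [0, 1].
#'
#' @param lst Land-surface-temperature `es_raster`, degrees C.
#' @param lulc LULC `es_raster` (supplies the cultivated reference mask).
#' @param mode `"intended"` (default) or `"printed"`.
#' @return Demand `es_raster` in [0, 1].
#' @export
heat_demand <- function(lst, lulc, mode = c("intended", "printed")) {
  mode <- match.arg(mode)
  check_coregistered(lst, lulc)
  t <- lst$values
  cult <- !is.na(lulc$values) & lulc$values == lulc_codes()[["cultivated"]] &
    !is.na(t)
  if (!any(cult)) stop("no cultivated pixels with finite LST")
  tref <- mean(t[cult])
  raw <- if (mode == "intended") pmax(t - tref, 0)
         else ifelse(t < tref, t - tref, 0)
  hmd <- minmax_matrix(raw, "heat demand")
  wrap_raster(hmd, lst, units = "1")
}
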