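#' Vegetation Condition Index over cultivated pixels
#'
#' Min-max rescaling of annual NDVI, computed over cultivated pixels only:
#' VCI_i = (NDVI_i - NDVI_min) / (NDVI_max - NDVI_min), in [0, 1].
#' Non-cultivated pixels are `NA`.
#'
#' @param ndvi NDVI `es_raster`; must be finite on cultivated pixels.
#' @param lulc LULC `es_raster` (codes of [lulc_codes()]).
#' @return VCI `es_raster` in [0, 1] on cultivated pixels.
#' @export
vci <- function(ndvi, lulc) {
  check_coregistered(ndvi, lulc)
  mask <- !is.na(lulc$values) & lulc$values == lulc_codes()[["cultivated"]]
  if (!any(mask)) stop("no cultivated pixels in LULC layer")
  nv <- ndvi$values[mask]
  if (anyNA(nv)) stop("NDVI is missing on some cultivated pixels")
  lo <- min(nv); hi <- max(nv)
  if (hi - lo <= 0)
    stop("degenerate NDVI range over cultivated pixels (constant NDVI)")
  out <- matrix(NA_real_, nrow(ndvi$values), ncol(ndvi$values))
  out[mask] <- (ndvi$values[mask] - lo) / (hi - lo)
  wrap_raster(out, ndvi, units = "1")
}

#' Crop-production supply: allocate the regional total by VCI share
#'
#' CP_i = GP_s * VCI_i / sum(VCI); the allocation conserves the regional
#' total exactly (to floating-point round-off). Nonzero only on cultivated
#' pixels.
#'
#' @param vci_layer Output of [vci()].
#' @param params A [crop_params()].
#' @return Supply `es_raster`, t/pixel.
#' @export
crop_supply <- function(vci_layer, params = crop_params()) {
  v <- vci_layer$values
  total_vci <- sum(v, na.rm = TRUE)
  if (!any(!is.na(v) & v > 0) || total_vci <= 0)
    stop("total VCI over cultivated pixels is zero; cannot allocate")
  out <- matrix(0, nrow(v), ncol(v))
  mask <- !is.na(v)
  out[mask] <- params$total_production * v[mask] / total_vci
  wrap_raster(out, vci_layer, units = "t/pixel")
}

#' Crop-production demand: population times per-capita consumption
#'
#' D_c,i = P_c,i * C_a.
#'
#' @param population Population `es_raster`, persons/pixel (>= 0).
#' @param params A [crop_params()].
#' @return Demand `es_raster`, t/pixel.
#' @export
crop_demand <- function(population, params = crop_params()) {
  p <- population$values
  if (any(p[!is.na(p)] < 0)) stop("negative population")
  wrap_raster(p * params$per_capita_consumption, population,
              units = "t/pixel")
}
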