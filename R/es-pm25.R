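#' PM2.5-reduction supply: annual dry deposition on forest canopy
#'
#' Per forest pixel: flux F = Vd * Ch * 3600 / 1e6 (g m-2 h-1), total canopy
#' leaf area TCLA = A * LAI (A = pixel area), daily capture
#' Qd = F * TCLA * T * (1 - R) and annual capture Qy = D * Qd. The hourly
#' concentration Ch is taken equal to the annual-mean concentration raster.
#' Non-forest pixels supply 0.
#'
#' @param pm25 Annual-mean PM2.5 concentration `es_raster`, ug/m3 (>= 0).
#' @param lai Leaf-area index `es_raster` (>= 0).
#' @param lulc LULC `es_raster`.
#' @param params A [pm25_params()].
#' @return Supply `es_raster`, g/pixel/yr.
#' @export
pm25_supply <- function(pm25, lai, lulc, params = pm25_params()) {
  check_coregistered(pm25, lai, lulc)
  conc <- pm25$values
  if (any(conc[!is.na(conc)] < 0)) stop("negative PM2.5 concentration")
  forest <- !is.na(lulc$values) & lulc$values == lulc_codes()[["forest"]]
  A <- cell_area(pm25$spec)
  flux <- params$deposition_velocity * conc * 3600 / 1e6
  qy <- params$non_rainy_days * flux * (A * lai$values) *
    params$hours_per_day * (1 - params$resuspension)
  out <- matrix(0, nrow(conc), ncol(conc))
  out[forest] <- qy[forest]
  out[is.na(conc) | (forest & is.na(lai$values))] <- NA_real_
  wrap_raster(out, pm25, units = "g/pixel/yr")
}

#' PM2.5-reduction demand: annual exceedance over the permitted level
#'
#' D_i = (Ca - permitted) * H * A * 365 * 24 where the annual mean Ca exceeds
#' the permitted concentration, else 0. H is the boundary-layer height and A
#' the pixel area, so the demand is the annual pollutant mass, above the
#' guideline, in the air column over the pixel.
#'
#' @param pm25 Annual-mean PM2.5 concentration `es_raster`, ug/m3.
#' @param params A [pm25_params()].
#' @return Demand `es_raster`, ug/pixel/yr.
#' @export
pm25_demand <- function(pm25, params = pm25_params()) {
  conc <- pm25$values
  A <- cell_area(pm25$spec)
  exceed <- pmax(conc - params$permitted, 0)
  wrap_raster(exceed * params$boundary_height * A * 365 * 24, pm25,
              units = "ug/pixel/yr")
}
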