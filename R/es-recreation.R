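#' Landscape-recreation supply: green share of each subdistrict
#'
#' S_r = (forest + grassland area) / (subdistrict area), in [0, 1], computed
#' per zone and broadcast back to the zone's pixels for raster output.
#'
#' @param lulc LULC `es_raster`.
#' @param zone_raster Subdistrict zone `es_raster`.
#' @return Supply `es_raster`, m2/m2 in [0, 1].
#' @export
recreation_supply <- function(lulc, zone_raster) {
  check_coregistered(lulc, zone_raster)
  lu <- lulc$values; zr <- zone_raster$values
  ok <- !is.na(lu) & !is.na(zr)
  if (!any(ok)) stop("no pixels with both LULC and zone defined")
  green <- lu %in% lulc_codes()[c("forest", "grassland")]
  zf <- factor(zr[ok])
  share <- tapply(green[ok], zf, mean)
  out <- matrix(NA_real_, nrow(lu), ncol(lu))
  out[ok] <- share[as.character(zr[ok])]
  wrap_raster(out, lulc, units = "m2/m2")
}

#' Landscape-recreation demand: planned per-capita green area
#'
#' D_r = population density (persons/m2) times the planned per-capita green
#' area (m2/person).
#'
#' @param pop_density Population-density `es_raster`, persons/m2 (>= 0).
#' @param params A [recreation_params()].
#' @return Demand `es_raster`, m2/m2.
#' @export
recreation_demand <- function(pop_density, params = recreation_params()) {
  d <- pop_density$values
  if (any(d[!is.na(d)] < 0)) stop("negative population density")
  wrap_raster(d * params$per_capita_green, pop_density, units = "m2/m2")
}

#' Quantify all six services on a landscape stack
#'
#' Convenience wrapper producing the twelve supply/demand rasters from a
#' generated or loaded stack. Subdistrict-level services (water demand,
#' recreation supply) use the village zone raster.
#'
#' @param stack A `landscape_stack` with layers lulc, population, elderly,
#'   children, ndvi, precip, pet, awc, hsg, pm25, lai, lst, impervious and a
#'   `water_use` table.
#' @param village_zones Village zone `es_raster`.
#' @param params Output of [default_params()] (or an edited copy). When
#'   omitted, defaults are used, with the crop total and non-rainy days
#'   taken from the stack's `constants` table if the stack was generated.
#' @param hm_demand_mode Passed to [heat_demand()].
#' @return Named list of services `CP, WR, PR, FM, HM, LR`, each
#'   `list(supply =, demand =)`.
#' @export
quantify_services <- function(stack, village_zones, params = NULL,
                              hm_demand_mode = "intended") {
  if (is.null(params)) {
    params <- default_params()
    const <- stack$tables$constants
    if (!is.null(const)) {
      get_const <- function(nm) const$value[match(nm, const$name)]
      if (!is.na(get_const("total_crop_production")))
        params$crop$total_production <- get_const("total_crop_production")
      if (!is.na(get_const("non_rainy_days")))
        params$pm25$non_rainy_days <- get_const("non_rainy_days")
    }
  }
  lulc <- stack_layer(stack, "lulc")
  pop <- stack_layer(stack, "population")
  v <- vci(stack_layer(stack, "ndvi"), lulc)
  dens <- wrap_raster(pop$values / cell_area(stack$spec), pop,
                      units = "person/m2")
  yld <- water_yield(stack_layer(stack, "precip"), stack_layer(stack, "pet"),
                     stack_layer(stack, "awc"), lulc, params$water)
  list(
    CP = list(supply = crop_supply(v, params$crop),
              demand = crop_demand(pop, params$crop)),
    WR = list(supply = water_retention_supply(yld,
                stack_layer(stack, "precip"), lulc, params$water),
              demand = water_demand(lulc, pop, stack$tables$water_use,
                                    village_zones, params$water)),
    PR = list(supply = pm25_supply(stack_layer(stack, "pm25"),
                                   stack_layer(stack, "lai"), lulc,
                                   params$pm25),
              demand = pm25_demand(stack_layer(stack, "pm25"), params$pm25)),
    FM = list(supply = flood_supply(lulc, stack_layer(stack, "hsg"),
                                    params$flood),
              demand = flood_demand(pop, stack_layer(stack, "elderly"),
                                    stack_layer(stack, "children"),
                                    stack_layer(stack, "impervious"), lulc,
                                    params$flood)),
    HM = list(supply = heat_supply(lulc, stack_layer(stack, "pet"),
                                   params$heat),
              demand = heat_demand(stack_layer(stack, "lst"), lulc,
                                   mode = hm_demand_mode)),
    LR = list(supply = recreation_supply(lulc, village_zones),
              demand = recreation_demand(dens, params$recreation)))
}
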