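#' Annual water yield (Budyko curve with a runoff-free vegetation branch)
#'
#' On vegetated classes (lulc_veg = 1) the yield is Y = (1 - AET/P) * P with
#' AET/P = (1 + wR) / (1 + wR + 1/R), where the dryness index R = Kc * ET0 / P
#' and w = Z * AWC / P + 1.25 (a direct `w` raster may be supplied instead).
#' On non-vegetated classes AET = min(Kc * ET0, P) and Y = P - AET, so yield
#' never goes negative.
#'
#' @param precip Annual precipitation `es_raster`, mm; must be > 0 on
#'   vegetated pixels.
#' @param pet Reference potential evapotranspiration ET0 `es_raster`, mm.
#' @param awc Plant-available water content `es_raster`, mm (ignored where a
#'   `w` raster is given).
#' @param lulc LULC `es_raster`.
#' @param params A [water_params()]; `coef` must cover every LULC code
#'   present.
#' @param w Optional `es_raster` of the Budyko shape parameter, overriding
#'   the Z * AWC / P + 1.25 parameterization.
#' @return Yield `es_raster`, mm. AET/P stays strictly inside (0, 1) on
#'   vegetated pixels.
#' @export
water_yield <- function(precip, pet, awc, lulc, params = water_params(),
                        w = NULL) {
  check_coregistered(precip, pet, awc, lulc)
  lu <- lulc$values
  codes <- sort(unique(lu[!is.na(lu)]))
  if (!all(codes %in% params$coef$lucode))
    stop("LULC code(s) missing from the water coefficient table: ",
         paste(setdiff(codes, params$coef$lucode), collapse = ", "))
  idx <- match(lu, params$coef$lucode)
  kc <- matrix(params$coef$kc[idx], nrow(lu), ncol(lu))
  veg <- matrix(params$coef$lulc_veg[idx], nrow(lu), ncol(lu))
  P <- precip$values; et0 <- pet$values
  if (any(veg == 1L & !is.na(P) & P <= 0, na.rm = TRUE))
    stop("nonpositive precipitation on a vegetated pixel")
  out <- matrix(NA_real_, nrow(lu), ncol(lu))
  vm <- !is.na(veg) & veg == 1L & !is.na(P) & !is.na(et0)
  if (any(vm)) {
    R <- kc[vm] * et0[vm] / P[vm]
    wv <- if (is.null(w)) {
      if (anyNA(awc$values[vm])) stop("AWC missing on vegetated pixels")
      params$budyko_z * awc$values[vm] / P[vm] + 1.25
    } else w$values[vm]
    aet_ratio <- (1 + wv * R) / (1 + wv * R + 1 / R)
    out[vm] <- (1 - aet_ratio) * P[vm]
  }
  nm <- !is.na(veg) & veg == 0L & !is.na(P) & !is.na(et0)
  out[nm] <- P[nm] - pmin(kc[nm] * et0[nm], P[nm])
  wrap_raster(out, precip, units = "mm")
}

#' Water-retention supply: yield minus surface runoff
#'
#' WR = Y - P * C_j with the per-LULC surface runoff coefficient C_j.
#' Sealed classes (C_j = 1) can make WR negative; negatives propagate unless
#' `params$clamp_negative` is set.
#'
#' @param yield_layer Output of [water_yield()], mm.
#' @param precip Annual precipitation `es_raster`, mm.
#' @param lulc LULC `es_raster`.
#' @param params A [water_params()].
#' @return Supply `es_raster`, mm (multiply by cell area / 1000 for m3).
#' @export
water_retention_supply <- function(yield_layer, precip, lulc,
                                   params = water_params()) {
  check_coregistered(yield_layer, precip, lulc)
  idx <- match(lulc$values, params$coef$lucode)
  if (any(is.na(idx) & !is.na(lulc$values)))
    stop("LULC code missing from the water coefficient table")
  cj <- matrix(params$coef$c_j[idx], nrow(lulc$values), ncol(lulc$values))
  wr <- yield_layer$values - precip$values * cj
  if (params$clamp_negative) wr <- pmax(wr, 0)
  wrap_raster(wr, yield_layer, units = "mm")
}

#' Water demand: domestic + agricultural + industrial + ecological use
#'
#' Domestic demand is W_c per person on every pixel. The subdistrict table's
#' agricultural, industrial and ecological totals are spread uniformly over
#' that subdistrict's cultivated, built-up (industrial) and forest+grassland
#' pixels respectively; each component conserves its table total exactly.
#'
#' @param lulc LULC `es_raster`.
#' @param population Population `es_raster`, persons/pixel.
#' @param use_table Data frame with columns `zone_id`, `agricultural`,
#'   `industrial`, `ecological` (annual totals, m3, per subdistrict).
#' @param zone_raster Subdistrict zone `es_raster` (same ids as `use_table`).
#' @param params A [water_params()].
#' @param industrial_mask Optional logical matrix restricting the pixels that
#'   receive industrial use (default: all built-up pixels).
#' @return Demand `es_raster`, m3/pixel.
#' @export
water_demand <- function(lulc, population, use_table, zone_raster,
                         params = water_params(), industrial_mask = NULL) {
  check_coregistered(lulc, population, zone_raster)
  lu <- lulc$values
  codes <- lulc_codes()
  dem <- params$per_capita_domestic * population$values
  dem[is.na(dem)] <- 0
  masks <- list(
    agricultural = lu == codes[["cultivated"]],
    industrial   = if (is.null(industrial_mask)) lu == codes[["builtup"]]
                   else industrial_mask,
    ecological   = lu %in% codes[c("forest", "grassland")])
  zr <- zone_raster$values
  for (comp in names(masks)) {
    m <- masks[[comp]] & !is.na(lu)
    for (i in seq_len(nrow(use_table))) {
      total <- use_table[[comp]][i]
      if (is.na(total) || total == 0) next
      sel <- m & !is.na(zr) & zr == use_table$zone_id[i]
      n <- sum(sel)
      if (n == 0L)
        stop(sprintf(
          "subdistrict %s has %s water use %.6g m3 but no %s pixels",
          use_table$zone_id[i], comp, total,
          c(agricultural = "cultivated", industrial = "industrial",
            ecological = "forest/grassland")[comp]))
      dem[sel] <- dem[sel] + total / n
    }
  }
  dem[is.na(lu)] <- NA_real_
  wrap_raster(dem, lulc, units = "m3/pixel")
}
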