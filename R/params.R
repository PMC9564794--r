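#' Land-use / land-cover class codes
#'
#' The six-class LULC legend used throughout: 1 cultivated land, 2 forest,
#' 3 grassland, 4 water area, 5 built-up area, 6 unused land.
#' @return Named integer vector of class codes.
#' @export
lulc_codes <- function() {
  c(cultivated = 1L, forest = 2L, grassland = 3L, water = 4L,
    builtup = 5L, unused = 6L)
}

#' Crop-production parameters
#'
#' @param total_production Regional total crop production GP_s to be allocated
#'   over cultivated pixels, tonnes. Default 2.09e6 t.
#' @param per_capita_consumption Per-capita annual crop consumption C_a,
#'   t/person. Default 0.1221.
#' @export
crop_params <- function(total_production = 2.09e6,
                        per_capita_consumption = 0.1221) {
  stopifnot(total_production > 0, per_capita_consumption > 0)
  structure(list(total_production = total_production,
                 per_capita_consumption = per_capita_consumption),
            class = "crop_params")
}

#' Water-retention parameters (biophysical coefficient table)
#'
#' Per-LULC coefficients: crop coefficient `kc`, maximum root depth (mm),
#' vegetation flag `lulc_veg` (1 = the Budyko curve applies, 0 = direct
#' evaporation cap), and surface runoff coefficient `c_j` in [0, 1].
#'
#' @param coef Data frame with columns lucode, kc, root_depth, lulc_veg, c_j;
#'   default is the standard six-class coefficient table.
#' @param budyko_z Dimensionless seasonality constant Z of the
#'   plant-available-water term w = Z * AWC / P + 1.25 (default 5).
#' @param per_capita_domestic Per-capita annual domestic water use W_c,
#'   m3/person (default 60).
#' @param clamp_negative If TRUE, negative water-retention supply (runoff
#'   exceeding yield, e.g. on sealed surfaces) is clamped at 0. Default FALSE:
#'   negatives are reported as generated.
#' @export
water_params <- function(coef = NULL, budyko_z = 5,
                         per_capita_domestic = 60, clamp_negative = FALSE) {
  if (is.null(coef)) {
    coef <- data.frame(
      lucode    = 1:6,
      kc        = c(0.6, 1, 0.65, 1, 0.3, 0.2),
      root_depth = c(1000, 7000, 1500, 1000, 500, 10),
      lulc_veg  = c(1L, 1L, 1L, 0L, 0L, 0L),
      c_j       = c(0.347, 0.0267, 0.0937, 0, 1, 1))
  }
  stopifnot(all(coef$kc > 0), all(coef$c_j >= 0 & coef$c_j <= 1),
            all(coef$lulc_veg %in% c(0L, 1L)), budyko_z >= 0,
            per_capita_domestic >= 0)
  structure(list(coef = coef, budyko_z = budyko_z,
                 per_capita_domestic = per_capita_domestic,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "water_params")
}

#' PM2.5-reduction parameters
#'
#' @param deposition_velocity Dry deposition velocity V_d, m/s (default 9e-4).
#' @param resuspension Resuspension rate R, fraction in [0, 1) (default 0.03).
#' @param hours_per_day Evaluation hours per day T (default 24).
#' @param non_rainy_days Number of non-rainy days D per year (default 245).
#' @param permitted Permitted annual-mean concentration threshold, ug/m3
#'   (default 10, the WHO guideline).
#' @param boundary_height Atmospheric boundary-layer height H, m (default 200).
#' @export
pm25_params <- function(deposition_velocity = 0.0009, resuspension = 0.03,
                        hours_per_day = 24, non_rainy_days = 245,
                        permitted = 10, boundary_height = 200) {
  stopifnot(deposition_velocity > 0, resuspension >= 0, resuspension < 1,
            permitted >= 0, non_rainy_days >= 0, boundary_height > 0)
  structure(list(deposition_velocity = deposition_velocity,
                 resuspension = resuspension, hours_per_day = hours_per_day,
                 non_rainy_days = non_rainy_days, permitted = permitted,
                 boundary_height = boundary_height),
            class = "pm25_params")
}

#' Flood-mitigation parameters
#'
#' @param design_storm Design storm depth P, mm (default 100).
#' @param cn_table Curve numbers per LULC (rows, lucode 1..6) and hydrologic
#'   soil group (columns A..D); default is the standard six-class table.
#'   CN = 0 (water) is treated as infinite retention (supply 1).
#' @param developed_scores Economic vulnerability scores of developed
#'   (built-up) pixels for the four impervious-density classes: open
#'   (a_ISA <= 20%), low (<= 50%), moderate (<= 80%), high (> 80%).
#' @param lulc_scores Economic scores of the non-developed classes, named by
#'   LULC code: cultivated 3, forest 1, grassland 2, water 1, unused 4.
#' @param a,b Weights of the population and economic vulnerability indices
#'   (default 1/2 each; must sum to 1).
#' @param alpha,beta,gamma Weights of total, elderly and child population
#'   density in the population vulnerability index (default 1/3 each).
#' @export
flood_params <- function(design_storm = 100, cn_table = NULL,
                         developed_scores = c(open = 5, low = 6,
                                              moderate = 7, high = 8),
                         lulc_scores = c(`1` = 3, `2` = 1, `3` = 2,
                                         `4` = 1, `6` = 4),
                         a = 0.5, b = 0.5,
                         alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  if (is.null(cn_table)) {
    cn_table <- rbind(
      `1` = c(54, 70, 80, 84),   # cultivated
      `2` = c(36, 60, 73, 79),   # forest
      `3` = c(49, 69, 79, 84),   # grassland
      `4` = c(0, 0, 0, 0),       # water
      `5` = c(85, 90, 92, 94),   # built-up
      `6` = c(77, 86, 91, 94))   # unused
    colnames(cn_table) <- c("A", "B", "C", "D")
  }
  stopifnot(design_storm > 0, all(cn_table >= 0 & cn_table <= 100),
            abs(a + b - 1) < 1e-12, abs(alpha + beta + gamma - 1) < 1e-12)
  structure(list(design_storm = design_storm, cn_table = cn_table,
                 developed_scores = developed_scores,
                 lulc_scores = lulc_scores, a = a, b = b,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "flood_params")
}

#' Heat-mitigation parameters
#'
#' @param coef Per-LULC table with columns lucode, shade, kc, albedo, g
#'   (green-space indicator); default is the standard six-class table.
#' @param dcool Cooling distance of a green space, m (default 450).
#' @param large_green_area Minimum connected green-patch area, m2, for a
#'   pixel to keep its own cooling capacity (default 20000).
#' @param weights Weights of shade, evapotranspiration index and albedo in
#'   the cooling-capacity index (default 0.6, 0.2, 0.2).
#' @export
heat_params <- function(coef = NULL, dcool = 450, large_green_area = 20000,
                        weights = c(shade = 0.6, eti = 0.2, albedo = 0.2)) {
  if (is.null(coef)) {
    coef <- data.frame(
      lucode = 1:6,
      shade  = c(0, 1, 0, 0, 0, 0),
      kc     = c(0.6, 1, 0.65, 1, 0.3, 0.2),
      albedo = c(0.2, 0.2, 0.2, 0.05, 0.15, 0.25),
      g      = c(1L, 1L, 1L, 0L, 0L, 0L))
  }
  stopifnot(all(coef$shade >= 0 & coef$shade <= 1),
            all(coef$albedo >= 0 & coef$albedo <= 1),
            all(coef$g %in% c(0L, 1L)), dcool > 0,
            abs(sum(weights) - 1) < 1e-12)
  structure(list(coef = coef, dcool = dcool,
                 large_green_area = large_green_area, weights = weights),
            class = "heat_params")
}

#' Landscape-recreation parameters
#'
#' @param per_capita_green Government-planned per-capita green area,
#'   m2/person (default 13).
#' @export
recreation_params <- function(per_capita_green = 13) {
  stopifnot(per_capita_green > 0)
  structure(list(per_capita_green = per_capita_green),
            class = "recreation_params")
}

#' Default parameter blocks for all six services
#' @return Named list of the six parameter objects with their defaults.
#' @export
default_params <- function() {
  list(crop = crop_params(), water = water_params(), pm25 = pm25_params(),
       flood = flood_params(), heat = heat_params(),
       recreation = recreation_params())
}
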