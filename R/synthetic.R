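#' Configuration of the synthetic landscape generator
#'
#' The generator emulates the full input suite of the supply-demand analysis
#' on a rapidly urbanizing landscape: a patchy six-class LULC mosaic,
#' population decaying from urban cores, a monotone NW-to-SE PM2.5 gradient,
#' land-surface temperature positively coupled to the impervious fraction,
#' smooth climate and soil fields, a nested county/township/village polygon
#' hierarchy built by recursive rectangular splitting with jittered
#' boundaries, and a per-village water-use table. Defaults depict a humid
#' subtropical urbanizing region: class weights 31.32% cultivated / 23.1%
#' built-up / 22.56% water with the remainder split over forest, grassland
#' and unused land; mean annual precipitation 1093 mm; mean population
#' density 1439 persons/km2.
#'
#' @param spec `grid_spec` of the target grid (default 200 x 200 at 30 m).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param n_counties,townships_per_county,villages_per_township Hierarchy
#'   shape (defaults 4 / 4 / 4, i.e. 64 villages).
#' @param lulc_class_weights Named proportions over the six classes; must
#'   sum to 1.
#' @param urban_core_centers Two-column matrix of core positions as (row,
#'   col) fractions of the grid.
#' @param pop_mean_density Mean population density, persons/km2.
#' @param pop_core_strength Relative amplitude of the urban-core population
#'   peaks.
#' @param pm25_mean,pm25_gradient Mean annual PM2.5 (ug/m3) and half-range
#'   of its NW-to-SE gradient.
#' @param lst_base,lst_impervious_coupling LST level (deg C) and the slope
#'   on the impervious fraction (> 0).
#' @param precip_mean,precip_sd,pet_mean,pet_sd,temp_mean,temp_sd,wind_mean,
#'   wind_sd,solar_mean,solar_sd Climate field means / spatial sds.
#' @param awc_mean,awc_sd Plant-available water content, mm.
#' @param elderly_frac,child_frac Elderly / child shares of population.
#' @param total_crop_production Crop total to allocate over the landscape,
#'   t. Default `NULL` scales the reference regional total (2.09e6 t over
#'   the 31.32% cultivated share of a 17,700 km2 region, i.e. a yield of
#'   about 377 t per km2 of cropland) to the landscape's expected
#'   cultivated area, preserving the region's overall supply-demand
#'   balance at any grid size.
#' @param non_rainy_days Non-rainy days per year (config scalar, default
#'   245).
#' @param agri_rate,ind_rate,eco_rate Water-use intensities, m3 per
#'   cultivated / built-up / green pixel and year.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(spec = grid_spec(200, 200), seed = 1,
                             n_counties = 4, townships_per_county = 4,
                             villages_per_township = 4,
                             lulc_class_weights = c(cultivated = 0.3132,
                                                    forest = 0.13,
                                                    grassland = 0.06,
                                                    water = 0.2256,
                                                    builtup = 0.231,
                                                    unused = 0.0402),
                             urban_core_centers = rbind(c(0.32, 0.30),
                                                        c(0.68, 0.72)),
                             pop_mean_density = 1439,
                             pop_core_strength = 25,
                             pm25_mean = 35, pm25_gradient = 15,
                             lst_base = 28, lst_impervious_coupling = 8,
                             precip_mean = 1093, precip_sd = 40,
                             pet_mean = 1000, pet_sd = 40,
                             temp_mean = 16.2, temp_sd = 0.5,
                             wind_mean = 3, wind_sd = 0.3,
                             solar_mean = 1400, solar_sd = 80,
                             awc_mean = 150, awc_sd = 25,
                             elderly_frac = 0.18, child_frac = 0.12,
                             total_crop_production = NULL,
                             non_rainy_days = 245,
                             agri_rate = 405, ind_rate = 200,
                             eco_rate = 50) {
  stopifnot(inherits(spec, "grid_spec"),
            abs(sum(lulc_class_weights) - 1) < 1e-9,
            all(lulc_class_weights >= 0),
            n_counties >= 1, townships_per_county >= 1,
            villages_per_township >= 1,
            all(c(precip_sd, pet_sd, temp_sd, wind_sd, solar_sd,
                  awc_sd) >= 0))
  cfg <- as.list(environment())
  if (is.null(cfg$total_crop_production)) {
    area_km2 <- spec$n_rows * spec$n_cols * cell_area(spec) / 1e6
    yield_per_km2 <- 2.09e6 / (17700 * 0.3132)   # t per km2 of cropland
    cfg$total_crop_production <-
      yield_per_km2 * area_km2 * lulc_class_weights[["cultivated"]]
  }
  structure(cfg, class = "landscape_config")
}

#' Generate a complete synthetic landscape
#'
#' Deterministic for a fixed seed: one seeded generator is threaded through
#' every draw. The produced stack always satisfies the preconditions of the
#' service-quantification stage (positive precipitation, finite NDVI on
#' cultivated pixels, covered coefficient tables, nonzero water-use targets
#' only where target pixels exist).
#'
#' @param config A [landscape_config()].
#' @return List with `stack` (a `landscape_stack`, 22 layers + the
#'   `water_use` table) and `hierarchy` (an `admin_hierarchy`).
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, generate_landscape_impl(config))
}

generate_landscape_impl <- function(cfg) {
  spec <- cfg$spec
  nr <- spec$n_rows; nc <- spec$n_cols; npix <- nr * nc
  n_villages <- cfg$n_counties * cfg$townships_per_county *
    cfg$villages_per_township
  if (npix / n_villages < 9)
    stop("grid too small to host ", n_villages, " villages")

  hier <- build_hierarchy(spec, cfg$n_counties, cfg$townships_per_county,
                          cfg$villages_per_township)

  core <- core_kernel(spec, cfg$urban_core_centers)
  lulc_m <- generate_lulc(spec, cfg$lulc_class_weights, core)
  codes <- lulc_codes()
  cult <- lulc_m == codes[["cultivated"]]
  green <- lulc_m %in% codes[c("forest", "grassland")]
  built <- lulc_m == codes[["builtup"]]
  water <- lulc_m == codes[["water"]]

  # population: urban-core peaks over a low rural floor, suppressed on water
  relpop <- 0.12 + cfg$pop_core_strength * core +
    0.25 * abs(gaussian_field(nr, nc, 12))
  relpop[water] <- relpop[water] * 0.01
  pop_per_pixel <- cfg$pop_mean_density * cell_area(spec) / 1e6
  pop <- relpop * (pop_per_pixel * npix / sum(relpop))
  elderly <- cfg$elderly_frac * pop *
    pmax(0.5, 1 + 0.1 * gaussian_field(nr, nc, 10))
  children <- cfg$child_frac * pop *
    pmax(0.5, 1 + 0.1 * gaussian_field(nr, nc, 10))

  ndvi <- pmin(pmax(0.55 + 0.15 * gaussian_field(nr, nc, 15), 0.05), 0.95)
  precip <- pmax(cfg$precip_mean + cfg$precip_sd * gaussian_field(nr, nc, 25),
                 50)
  pet <- pmax(cfg$pet_mean + cfg$pet_sd * gaussian_field(nr, nc, 25), 50)
  awc <- pmax(cfg$awc_mean + cfg$awc_sd * gaussian_field(nr, nc, 20), 10)
  temperature <- cfg$temp_mean + cfg$temp_sd * gaussian_field(nr, nc, 25) +
    1.5 * core / max(core)
  wind <- pmax(cfg$wind_mean + cfg$wind_sd * gaussian_field(nr, nc, 25), 0.2)
  solar <- cfg$solar_mean + cfg$solar_sd * gaussian_field(nr, nc, 25)

  # impervious fraction by class, densest at the cores
  coren <- core / max(core)
  imperv <- matrix(0.02, nr, nc)
  imperv[cult] <- 0.05
  imperv[water] <- 0
  imperv[lulc_m == codes[["unused"]]] <- 0.1
  imperv[built] <- 0.55 + 0.4 * coren[built]
  imperv <- pmin(pmax(imperv + 0.05 * gaussian_field(nr, nc, 8), 0), 1)
  imperv[water] <- 0
  nis <- pmax(0.25 * imperv * (0.5 + 0.5 * matrix(stats::runif(npix), nr)), 0)

  lst <- cfg$lst_base + cfg$lst_impervious_coupling * imperv +
    1.5 * coren + 0.8 * gaussian_field(nr, nc, 12)

  # NW -> SE gradient: highest at the northwest corner (row 1, col 1)
  gNW <- (outer((nr - seq_len(nr)) / max(nr - 1, 1),
                (nc - seq_len(nc)) / max(nc - 1, 1), `+`)) / 2
  pm25 <- pmax(cfg$pm25_mean + cfg$pm25_gradient * (2 * gNW - 1) +
                 1.5 * gaussian_field(nr, nc, 20), 0)

  lai <- matrix(0.2, nr, nc)
  lai[cult] <- 3
  lai[lulc_m == codes[["forest"]]] <- 4.5
  lai[lulc_m == codes[["grassland"]]] <- 1.5
  lai[built] <- 0.3
  lai[water] <- 0
  lai <- pmax(lai * pmax(0.4, 1 + 0.15 * gaussian_field(nr, nc, 10)), 0)

  westness <- matrix((nc - seq_len(nc)) / max(nc - 1, 1), nr, nc,
                     byrow = TRUE)
  dem <- pmax(20 + 30 * westness + 12 * gaussian_field(nr, nc, 30), 0)
  slope <- slope_from_dem(dem, spec$cell_size)
  roughness <- local_sd3(dem)

  gdp <- pmax(5000 * coren + 3000 * imperv +
                400 * abs(gaussian_field(nr, nc, 15)), 0)

  # soil texture: three smooth fields through a softmax, in percent
  e1 <- exp(0.8 * gaussian_field(nr, nc, 30))
  e2 <- exp(0.8 * gaussian_field(nr, nc, 30))
  e3 <- exp(0.8 * gaussian_field(nr, nc, 30))
  tot <- e1 + e2 + e3
  sand <- 100 * e1 / tot; silt <- 100 * e2 / tot; clay <- 100 * e3 / tot
  # hydrologic soil groups: sandier soils infiltrate better (A), clayey D
  hsg <- matrix(5L - discretize(as.vector(sand), 4), nr, nc)

  zr_village <- rasterize_hierarchy(hier, spec)$village
  stack <- landscape_stack(spec, layers = list(
    lulc = es_raster(lulc_m, spec, "class"),
    population = es_raster(pop, spec, "person/pixel"),
    elderly = es_raster(elderly, spec, "person/pixel"),
    children = es_raster(children, spec, "person/pixel"),
    ndvi = es_raster(ndvi, spec, "1"),
    precip = es_raster(precip, spec, "mm"),
    pet = es_raster(pet, spec, "mm"),
    awc = es_raster(awc, spec, "mm"),
    temperature = es_raster(temperature, spec, "degC"),
    wind = es_raster(wind, spec, "m/s"),
    solar = es_raster(solar, spec, "kWh/m2"),
    impervious = es_raster(imperv, spec, "1"),
    nis = es_raster(nis, spec, "1"),
    lst = es_raster(lst, spec, "degC"),
    pm25 = es_raster(pm25, spec, "ug/m3"),
    lai = es_raster(lai, spec, "1"),
    dem = es_raster(dem, spec, "m"),
    slope = es_raster(slope, spec, "deg"),
    roughness = es_raster(roughness, spec, "m"),
    gdp = es_raster(gdp, spec, "unit/km2"),
    sand = es_raster(sand, spec, "%"),
    silt = es_raster(silt, spec, "%"),
    clay = es_raster(clay, spec, "%"),
    hsg = es_raster(hsg, spec, "class")),
    tables = list(
      water_use = water_use_table(lulc_m, zr_village$values, cfg),
      constants = data.frame(
        name = c("total_crop_production", "non_rainy_days"),
        value = c(cfg$total_crop_production, cfg$non_rainy_days))))
  list(stack = stack, hierarchy = hier)
}

# --- internal generator pieces -------------------------------------------

# Sum of isotropic Gaussian bumps at the urban cores (matrix over the grid).
core_kernel <- function(spec, centers) {
  nr <- spec$n_rows; nc <- spec$n_cols
  sigma <- 0.15 * min(nr, nc)
  k <- matrix(0, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1] * nr; c0 <- centers[i, 2] * nc
    k <- k + exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sigma^2))
  }
  k
}

# Spatially autocorrelated standard field: smoothed white noise rescaled to
# mean 0, sd 1. `range_cells` sets the correlation length.
gaussian_field <- function(nr, nc, range_cells) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  r <- max(1L, round(range_cells / 3))
  off <- (-(3 * r)):(3 * r)
  k1 <- exp(-off^2 / (2 * r^2))
  k <- outer(k1, k1)
  sm <- conv2_same(noise, k / sum(k))
  (sm - mean(sm)) / stats::sd(sm)
}

# Patch-growing LULC: class-labelled seed points, each pixel takes the class
# of its nearest seed. Seed class counts follow the weights exactly
# (largest-remainder), so realized class shares track the weights closely;
# built-up seeds are biased toward the urban cores.
generate_lulc <- function(spec, weights, core) {
  nr <- spec$n_rows; nc <- spec$n_cols; npix <- nr * nc
  codes <- lulc_codes()
  n_seeds <- max(sum(weights > 0), round(npix / 40))
  cnt <- largest_remainder(weights * n_seeds)
  # every positive-weight class keeps at least one seed when room allows
  for (i in which(weights > 0 & cnt == 0)) {
    donor <- which.max(cnt)
    if (cnt[donor] > 1) { cnt[donor] <- cnt[donor] - 1L; cnt[i] <- 1L }
  }
  classes <- rep(codes[names(weights)], cnt)
  pos <- integer(0)
  for (j in seq_along(cnt)) {
    if (cnt[j] == 0) next
    prob <- if (names(weights)[j] == "builtup") 1 + 8 * core / max(core)
            else rep(1, npix)
    pos <- c(pos, sample.int(npix, cnt[j], replace = FALSE,
                             prob = as.vector(prob)))
  }
  seed_r <- (pos - 1L) %% nr + 1L
  seed_c <- (pos - 1L) %/% nr + 1L
  S <- cbind(seed_r, seed_c)
  seed_sq <- seed_r^2 + seed_c^2
  P <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  nearest <- integer(npix)
  for (start in seq(1L, npix, by = 8000L)) {   # blockwise argmin distance
    idx <- start:min(start + 7999L, npix)
    score <- 2 * (P[idx, , drop = FALSE] %*% t(S))
    score <- sweep(score, 2, seed_sq)
    nearest[idx] <- max.col(score, ties.method = "first")
  }
  matrix(classes[nearest], nr, nc)
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  need <- round(sum(x)) - sum(fl)
  if (need > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

# Recursive halving of a rectangle into n jittered parts (exact count).
split_rect <- function(rect, n) {
  if (n == 1) return(list(rect))
  n1 <- n %/% 2; n2 <- n - n1
  w <- rect[3] - rect[1]; h <- rect[4] - rect[2]
  frac <- (n1 / n) * stats::runif(1, 0.85, 1.15)
  frac <- min(max(frac, 0.15), 0.85)
  if (w >= h) {
    cut <- rect[1] + frac * w
    c(split_rect(c(rect[1], rect[2], cut, rect[4]), n1),
      split_rect(c(cut, rect[2], rect[3], rect[4]), n2))
  } else {
    cut <- rect[2] + frac * h
    c(split_rect(c(rect[1], rect[2], rect[3], cut), n1),
      split_rect(c(rect[1], cut, rect[3], rect[4]), n2))
  }
}

rect_ring <- function(r) {
  rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4]),
        c(r[1], r[2]))
}

build_hierarchy <- function(spec, n_counties, townships_per_county,
                            villages_per_township) {
  x0 <- spec$origin_x; y1 <- spec$origin_y
  x1 <- x0 + spec$n_cols * spec$cell_size
  y0 <- y1 - spec$n_rows * spec$cell_size
  counties <- split_rect(c(x0, y0, x1, y1), n_counties)
  zones <- data.frame(level = character(), zone_id = integer(),
                      parent_id = integer())
  polygons <- list(county = list(), township = list(), village = list())
  vid <- 0L; tid <- 0L
  for (ci in seq_along(counties)) {
    zones <- rbind(zones, data.frame(level = "county", zone_id = ci,
                                     parent_id = NA_integer_))
    polygons$county[[as.character(ci)]] <- rect_ring(counties[[ci]])
    townships <- split_rect(counties[[ci]], townships_per_county)
    for (ti in seq_along(townships)) {
      tid <- tid + 1L
      zones <- rbind(zones, data.frame(level = "township", zone_id = tid,
                                       parent_id = ci))
      polygons$township[[as.character(tid)]] <- rect_ring(townships[[ti]])
      villages <- split_rect(townships[[ti]], villages_per_township)
      for (vi in seq_along(villages)) {
        vid <- vid + 1L
        zones <- rbind(zones, data.frame(level = "village", zone_id = vid,
                                         parent_id = tid))
        polygons$village[[as.character(vid)]] <- rect_ring(villages[[vi]])
      }
    }
  }
  admin_hierarchy(zones, polygons)
}

slope_from_dem <- function(dem, cell) {
  nr <- nrow(dem); nc <- ncol(dem)
  gx <- dem[, c(2:nc, nc)] - dem[, c(1, 1:(nc - 1))]
  gy <- dem[c(2:nr, nr), ] - dem[c(1, 1:(nr - 1)), ]
  atan(sqrt((gx / (2 * cell))^2 + (gy / (2 * cell))^2)) * 180 / pi
}

local_sd3 <- function(m) {
  k <- matrix(1 / 9, 3, 3)
  mu <- conv2_same(m, k)
  mu2 <- conv2_same(m^2, k)
  sqrt(pmax(mu2 - mu^2, 0))
}

# Per-village water-use totals; a component is nonzero only when the village
# has pixels of its target class, so downstream allocation never fails.
water_use_table <- function(lulc_m, zone_m, cfg) {
  codes <- lulc_codes()
  ids <- sort(unique(zone_m[!is.na(zone_m)]))
  n_of <- function(mask) {
    counts <- tapply(mask[!is.na(zone_m)],
                     factor(zone_m[!is.na(zone_m)], levels = ids), sum)
    counts[is.na(counts)] <- 0
    as.numeric(counts)
  }
  ncult <- n_of(lulc_m == codes[["cultivated"]])
  nbuilt <- n_of(lulc_m == codes[["builtup"]])
  ngreen <- n_of(lulc_m %in% codes[c("forest", "grassland")])
  u <- function(n) stats::runif(n, 0.8, 1.2)
  k <- length(ids)
  data.frame(zone_id = as.integer(ids),
             agricultural = cfg$agri_rate * ncult * u(k),
             industrial = cfg$ind_rate * nbuilt * u(k),
             ecological = cfg$eco_rate * ngreen * u(k))
}
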