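#' Plant bundle archetypes directly in ESDR space
#'
#' Builds a zones x services ESDR matrix whose rows cluster around k
#' archetype profiles: row i = archetype[label_i, ] + Gaussian noise. With
#' `noise_sd = 0` the zone vectors equal the archetypes exactly. Used for
#' controlled recovery experiments on the clustering and driver-attribution
#' stages.
#'
#' @param archetypes k x 6 matrix of target ESDR profiles (columns CP, WR,
#'   PR, FM, HM, LR).
#' @param n_zones Number of zones; labels are assigned round-robin so every
#'   archetype is populated (requires k <= n_zones).
#' @param noise_sd Sd of the iid Gaussian perturbation (default 0.05).
#' @param seed Integer seed.
#' @return List: `esdr` (n_zones x 6, zone ids 1..n as row names),
#'   `labels` (true archetype of each zone).
#' @export
plant_esdr_matrix <- function(archetypes, n_zones, noise_sd = 0.05,
                              seed = 1) {
  archetypes <- as.matrix(archetypes)
  k <- nrow(archetypes)
  stopifnot(k >= 2, noise_sd >= 0)
  if (k > n_zones) stop("more archetypes than zones")
  with_seed(seed, {
    labels <- sample(rep_len(1:k, n_zones))
    m <- archetypes[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_zones * ncol(archetypes), sd = noise_sd),
             n_zones)
    rownames(m) <- 1:n_zones
    if (is.null(colnames(archetypes)))
      colnames(m) <- c("CP", "WR", "PR", "FM", "HM", "LR")
    list(esdr = m, labels = stats::setNames(labels, rownames(m)))
  })
}

#' Plant bundle archetypes into the physical input layers
#'
#' Assigns each village zone one of k archetypes (a signed profile over the
#' six services) and perturbs the layers that drive each service inside the
#' zone: NDVI (crop supply), population (crop / recreation / flood demand
#' and domestic water), precipitation and the water-use table (water
#' budget), LAI and PM2.5 (air-quality budget), the hydrologic soil group
#' (flood supply) and LST (heat demand). A positive archetype entry pushes
#' the zone toward surplus for that service; `separation` scales the push.
#' Optionally a named driver layer is additionally shifted per zone in
#' proportion to the archetype label, planting a recoverable driver effect;
#' with `driver_effect = 0` the labels are independent of every driver.
#'
#' @param stack A generated `landscape_stack`.
#' @param hier Matching `admin_hierarchy`.
#' @param archetypes k x 6 signed profile matrix (entries in about
#'   [-1, 1]); k must not exceed the village count.
#' @param separation Nonnegative effect scale (default 1.5).
#' @param driver Optional stack layer name to tie to archetype membership.
#' @param driver_effect Effect size (in layer sds per unit label z-score).
#' @param seed Integer seed.
#' @return List: `stack` (perturbed), `labels` (true archetype per village
#'   zone id), `zone_raster` (village zones).
#' @export
plant_bundles <- function(stack, hier, archetypes, separation = 1.5,
                          driver = NULL, driver_effect = 0, seed = 1) {
  archetypes <- as.matrix(archetypes)
  k <- nrow(archetypes)
  if (is.null(colnames(archetypes)))
    colnames(archetypes) <- c("CP", "WR", "PR", "FM", "HM", "LR")
  stopifnot(separation >= 0, driver_effect >= 0)
  zr <- rasterize_hierarchy(hier, stack$spec)$village
  ids <- sort(unique(zr$values[!is.na(zr$values)]))
  if (k > length(ids)) stop("more archetypes than village zones")
  with_seed(seed, {
    labels <- stats::setNames(sample(rep_len(1:k, length(ids))), ids)
    stack <- perturb_layers(stack, zr, labels, archetypes, separation)
    if (!is.null(driver) && driver_effect > 0) {
      l <- stack_layer(stack, driver)
      v <- l$values
      lz <- as.numeric(scale(as.numeric(labels)))
      shift <- stats::setNames(driver_effect * stats::sd(v, na.rm = TRUE) * lz,
                               names(labels))
      zm <- zr$values
      ok <- !is.na(zm) & !is.na(v)
      v[ok] <- pmax(v[ok] + shift[as.character(zm[ok])], 0)
      stack$layers[[driver]] <- wrap_raster(v, l)
    }
    list(stack = stack, labels = labels, zone_raster = zr)
  })
}

perturb_layers <- function(stack, zr, labels, arche, sep) {
  zm <- zr$values
  lu <- stack_layer(stack, "lulc")$values
  codes <- lulc_codes()
  # per-pixel archetype row
  a_of <- function(svc) {
    col <- stats::setNames(arche[, svc][labels], names(labels))
    out <- matrix(NA_real_, nrow(zm), ncol(zm))
    ok <- !is.na(zm)
    out[ok] <- col[as.character(zm[ok])]
    out
  }
  mul <- function(v, a, rate) ifelse(is.na(a), v, v * exp(rate * sep * a))

  a_cp <- a_of("CP"); a_wr <- a_of("WR"); a_pr <- a_of("PR")
  a_fm <- a_of("FM"); a_hm <- a_of("HM"); a_lr <- a_of("LR")

  l <- stack$layers
  ndvi <- l$ndvi$values
  cult <- !is.na(lu) & lu == codes[["cultivated"]]
  ndvi[cult] <- pmin(pmax(mul(ndvi[cult], a_cp[cult], 0.25), 0.02), 0.98)
  l$ndvi <- wrap_raster(ndvi, l$ndvi)

  # demand-side population lever shared by crop, recreation and flood
  # demand: deficit-planted zones additionally receive in-migration (an
  # additive density term), since scaling a near-empty zone cannot create
  # demand
  a_dem <- (a_cp + a_lr + a_fm) / 3
  mean_pop <- mean(l$population$values, na.rm = TRUE)
  inflow <- ifelse(!is.na(a_dem) & a_dem < 0,
                   0.5 * sep * (-a_dem) * mean_pop, 0)
  for (nm in c("population", "elderly", "children")) {
    frac <- c(population = 1, elderly = 0.18, children = 0.12)[[nm]]
    l[[nm]] <- wrap_raster(mul(l[[nm]]$values, a_dem, -0.6) + frac * inflow,
                           l[[nm]])
  }

  l$precip <- wrap_raster(pmax(mul(l$precip$values, a_wr, 0.08), 50),
                          l$precip)
  l$lai <- wrap_raster(mul(l$lai$values, a_pr, 0.4), l$lai)
  l$pm25 <- wrap_raster(mul(l$pm25$values, a_pr, -0.3), l$pm25)
  l$lst <- wrap_raster(ifelse(is.na(a_hm), l$lst$values,
                              l$lst$values - 2.5 * sep * a_hm), l$lst)

  hsg <- l$hsg$values
  shift <- ifelse(is.na(a_fm), 0, round(pmin(pmax(sep * a_fm, -3), 3)))
  l$hsg <- wrap_raster(pmin(pmax(hsg - shift, 1), 4), l$hsg)

  # land-conversion lever: recreation (and with it flood/heat demand) is
  # compositional, so surplus zones green up some sealed pixels and deficit
  # zones seal some green ones
  lu2 <- stack_layer(stack, "lulc")$values
  a_comp <- (a_lr + a_fm + a_hm) / 3
  conv_p <- pmin(0.45, 0.12 * sep * abs(a_comp))
  conv_p[is.na(conv_p)] <- 0
  rand <- matrix(stats::runif(length(lu2)), nrow(lu2), ncol(lu2))
  green_px <- !is.na(lu2) & lu2 %in% codes[c("forest", "grassland")]
  built_px <- !is.na(lu2) & lu2 == codes[["builtup"]]
  to_built <- green_px & !is.na(a_comp) & a_comp < 0 & rand < conv_p
  to_green <- built_px & !is.na(a_comp) & a_comp > 0 & rand < conv_p
  # never convert a zone's last green / built-up pixel: the water-use table
  # allocates ecological / industrial totals over those classes
  keep_one <- function(conv, class_px) {
    for (z in unique(zm[conv])) {
      in_zone <- !is.na(zm) & zm == z
      if (!any(class_px & in_zone & !conv)) {
        first <- which(conv & in_zone)[1]
        conv[first] <- FALSE
      }
    }
    conv
  }
  to_built <- keep_one(to_built, green_px)
  to_green <- keep_one(to_green, built_px)
  lu2[to_built] <- codes[["builtup"]]
  lu2[to_green] <- codes[["grassland"]]
  imp <- l$impervious$values
  imp[to_built] <- 0.7
  imp[to_green] <- 0.05
  lai2 <- l$lai$values
  lai2[to_built] <- 0.3
  lai2[to_green] <- 1.5
  l$lulc <- wrap_raster(lu2, stack_layer(stack, "lulc"))
  l$impervious <- wrap_raster(imp, l$impervious)
  l$lai <- wrap_raster(lai2, l$lai)

  stack$layers <- l
  wu <- stack$tables$water_use
  f <- exp(-0.8 * sep * arche[, "WR"][labels[as.character(wu$zone_id)]])
  for (comp in c("agricultural", "industrial", "ecological"))
    wu[[comp]] <- wu[[comp]] * f
  stack$tables$water_use <- wu
  stack
}
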