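#' Build a validated run configuration
#'
#' Accepts a YAML file path or a nested list and merges it over the
#' defaults. Unknown keys are rejected. Blocks: `seed`; `landscape`
#' (arguments of [landscape_config()] except `spec`/`seed`, plus `n_rows`,
#' `n_cols`, `cell_size`); `params` (per-service scalar overrides);
#' `bundling` (`k`, `n_restarts`, `k_range_max`); `geodetector`
#' (`n_strata`, `n_perm`, `y_mode`); `toggles` (`hm_demand_mode`,
#' `wr_clamp`, `balance_band`).
#'
#' @param config `NULL` (all defaults), a file path, or a list.
#' @param seed Optional seed overriding the config's.
#' @return A fully defaulted `run_config` list.
#' @export
run_config <- function(config = NULL, seed = NULL) {
  defaults <- list(
    seed = 1L,
    landscape = list(n_rows = 200L, n_cols = 200L, cell_size = 30),
    params = list(crop = list(), water = list(), pm25 = list(),
                  flood = list(), heat = list(), recreation = list()),
    bundling = list(k = 6L, n_restarts = 25L, k_range_max = 10L),
    geodetector = list(n_strata = 5L, n_perm = 999L,
                       y_mode = "label-code"),
    toggles = list(hm_demand_mode = "intended", wr_clamp = FALSE,
                   balance_band = 0.1))
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  merged <- merge_config(defaults, config, path = "config")
  if (!is.null(seed)) merged$seed <- as.integer(seed)
  class(merged) <- "run_config"
  merged
}

merge_config <- function(defaults, user, path) {
  extra <- setdiff(names(user), names(defaults))
  # landscape/params blocks accept any constructor argument
  open_blocks <- c("config$landscape", "config$params$crop",
                   "config$params$water", "config$params$pm25",
                   "config$params$flood", "config$params$heat",
                   "config$params$recreation")
  if (length(extra) && !path %in% open_blocks)
    stop("unknown config key(s) under ", path, ": ",
         paste(extra, collapse = ", "))
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      out[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                paste0(path, "$", nm))
    else out[[nm]] <- user[[nm]]
  }
  out
}

config_params <- function(cfg) {
  p <- cfg$params
  list(crop = do.call(crop_params, p$crop),
       water = do.call(water_params,
                       c(p$water, list(clamp_negative = cfg$toggles$wr_clamp))),
       pm25 = do.call(pm25_params, p$pm25),
       flood = do.call(flood_params, p$flood),
       heat = do.call(heat_params, p$heat),
       recreation = do.call(recreation_params, p$recreation))
}

#' Run the full pipeline: generate, quantify, aggregate, bundle, drivers
#'
#' Every stage is a pure function of (inputs, config, seed); the run-level
#' seed is deterministically forked per stage, so re-running with the same
#' config reproduces byte-identical CSV outputs. The run directory receives
#' the stack (ASCII grids + manifest), the hierarchy GeoJSON, one budget
#' CSV per scale, bundle label/centroid/Z-profile CSVs, a factor-detection
#' CSV per scale, and `manifest.json` (config echo, seed, package version,
#' per-file checksums). At a scale with fewer zones than the configured k,
#' k is capped at the zone count and the cap is recorded.
#'
#' @param config Anything [run_config()] accepts.
#' @param out_dir Output directory (created).
#' @param seed Optional seed override.
#' @return Invisibly, a list with the in-memory stage results and paths.
#' @export
run_all <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config, seed)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ls_args <- cfg$landscape
  spec <- grid_spec(ls_args$n_rows, ls_args$n_cols, ls_args$cell_size)
  ls_args <- ls_args[setdiff(names(ls_args),
                             c("n_rows", "n_cols", "cell_size"))]
  lcfg <- do.call(landscape_config,
                  c(list(spec = spec, seed = fork_seed(cfg$seed, "generate")),
                    ls_args))
  gen <- generate_landscape(lcfg)
  stack_dir <- file.path(out_dir, "stack")
  write_landscape_stack(gen$stack, stack_dir)
  write_hierarchy_geojson(gen$hierarchy, file.path(out_dir,
                                                   "hierarchy.geojson"))

  zone_rasters <- rasterize_hierarchy(gen$hierarchy, spec)
  params <- config_params(cfg)
  params$pm25$non_rainy_days <- lcfg$non_rainy_days
  if (is.null(cfg$params$crop$total_production))
    params$crop$total_production <- lcfg$total_crop_production
  services <- quantify_services(gen$stack, zone_rasters$village, params,
                                hm_demand_mode = cfg$toggles$hm_demand_mode)
  for (svc in names(services)) {
    write_ascii_grid(services[[svc]]$supply,
                     file.path(out_dir, paste0(svc, "_supply.asc")))
    write_ascii_grid(services[[svc]]$demand,
                     file.path(out_dir, paste0(svc, "_demand.asc")))
  }

  budgets <- build_budget_tables(services, zone_rasters, gen$hierarchy,
                                 balance_band = cfg$toggles$balance_band)
  bundles <- list(); qtables <- list()
  for (lv in names(budgets)) {
    utils::write.csv(budgets[[lv]],
                     file.path(out_dir, paste0("budget_", lv, ".csv")),
                     row.names = FALSE)
    n_zones <- nrow(budgets[[lv]])
    k_eff <- min(cfg$bundling$k, n_zones)
    areas <- as.numeric(table(factor(
      zone_rasters[[lv]]$values[!is.na(zone_rasters[[lv]]$values)],
      levels = budgets[[lv]]$zone_id))) * cell_area(spec)
    b <- bundle_zones(budgets[[lv]], k = k_eff,
                      seed = fork_seed(cfg$seed, "bundle"),
                      n_restarts = cfg$bundling$n_restarts,
                      k_range = 2:min(cfg$bundling$k_range_max, n_zones - 1),
                      zone_areas = areas)
    b$k_requested <- cfg$bundling$k
    bundles[[lv]] <- b
    utils::write.csv(data.frame(zone_id = names(b$labels),
                                bundle = as.integer(b$labels)),
                     file.path(out_dir, paste0("bundles_", lv, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(bundle = seq_len(b$k),
                                area_share = b$area_share, b$centroids),
                     file.path(out_dir, paste0("centroids_", lv, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(bundle = seq_len(b$k), b$zscore_profiles),
                     file.path(out_dir, paste0("zscores_", lv, ".csv")),
                     row.names = FALSE)

    drv <- driver_table(gen$stack, zone_rasters[[lv]])
    n_strata_eff <- max(2L, min(cfg$geodetector$n_strata, n_zones %/% 2L))
    qt <- suppressWarnings(
      factor_detection(b, drv, n_strata = n_strata_eff,
                       n_perm = cfg$geodetector$n_perm,
                       seed = fork_seed(cfg$seed, "detect"),
                       y_mode = cfg$geodetector$y_mode))
    qt <- cbind(scale = lv, qt)
    qtables[[lv]] <- qt
    utils::write.csv(qt, file.path(out_dir, paste0("drivers_", lv, ".csv")),
                     row.names = FALSE)
  }

  csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("esbundles")),
    config = unclass(cfg),
    checksums = as.list(tools::md5sum(sort(csvs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = cfg, stack = gen$stack,
                 hierarchy = gen$hierarchy, zone_rasters = zone_rasters,
                 services = services, budgets = budgets, bundles = bundles,
                 qtables = qtables, out_dir = out_dir))
}
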