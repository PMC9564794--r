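# Shared fixtures: tiny grids built in code, plus one memoised mid-size
# synthetic landscape so expensive stages are generated once per run.

tiny_spec <- function(nr = 2, nc = 2, cell = 30) grid_spec(nr, nc, cell)

make_raster <- function(values, nr, nc, units = "", cell = 30) {
  es_raster(matrix(values, nr, nc), grid_spec(nr, nc, cell), units)
}

# constant-valued layer on a spec
const_raster <- function(value, spec, units = "") {
  es_raster(matrix(value, spec$n_rows, spec$n_cols), spec, units)
}

# Hand-built 2-county / 4-township / 8-village rectangular hierarchy over an
# extent [0, w] x [0, h]; each level splits its parent in half.
rect_hierarchy <- function(w = 240, h = 240) {
  rect <- function(x0, y0, x1, y1)
    rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
  zones <- data.frame(level = character(), zone_id = integer(),
                      parent_id = integer())
  polys <- list(county = list(), township = list(), village = list())
  tid <- 0L; vid <- 0L
  for (ci in 1:2) {                       # counties: west / east halves
    cx0 <- (ci - 1) * w / 2; cx1 <- ci * w / 2
    zones <- rbind(zones, data.frame(level = "county", zone_id = ci,
                                     parent_id = NA_integer_))
    polys$county[[as.character(ci)]] <- rect(cx0, 0, cx1, h)
    for (ti in 1:2) {                     # townships: south / north halves
      tid <- tid + 1L
      ty0 <- (ti - 1) * h / 2; ty1 <- ti * h / 2
      zones <- rbind(zones, data.frame(level = "township", zone_id = tid,
                                       parent_id = ci))
      polys$township[[as.character(tid)]] <- rect(cx0, ty0, cx1, ty1)
      for (vi in 1:2) {                   # villages: west / east halves
        vid <- vid + 1L
        vx0 <- cx0 + (vi - 1) * w / 4; vx1 <- cx0 + vi * w / 4
        zones <- rbind(zones, data.frame(level = "village", zone_id = vid,
                                         parent_id = tid))
        polys$village[[as.character(vid)]] <- rect(vx0, ty0, vx1, ty1)
      }
    }
  }
  admin_hierarchy(zones, polys)
}

# Memoised landscapes (generated once per test run).
.fixture_env <- new.env()

small_landscape <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- landscape_config(spec = grid_spec(80, 80), seed = 42,
                            n_counties = 2, townships_per_county = 2,
                            villages_per_township = 4)
    .fixture_env$small <- generate_landscape(cfg)
    .fixture_env$small$zones <-
      rasterize_hierarchy(.fixture_env$small$hierarchy, cfg$spec)
  }
  .fixture_env$small
}

full_landscape <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- landscape_config(spec = grid_spec(200, 200), seed = 11)
    .fixture_env$full <- generate_landscape(cfg)
    .fixture_env$full$zones <-
      rasterize_hierarchy(.fixture_env$full$hierarchy, cfg$spec)
  }
  .fixture_env$full
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
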