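#' Nested administrative hierarchy (county > township > village)
#'
#' Three ordered polygon levels with stable integer zone ids. Every village
#' has exactly one township parent and every township exactly one county
#' parent; zone ids are unique within a level.
#'
#' @param zones Data frame with columns `level` (one of "county", "township",
#'   "village"), `zone_id` (integer, unique within level) and `parent_id`
#'   (integer; `NA` for counties).
#' @param polygons Named list (by level) of named lists (by zone_id) of rings:
#'   each ring a 2-column matrix of projected x, y vertices.
#' @return An object of class `admin_hierarchy`.
#' @export
admin_hierarchy <- function(zones, polygons) {
  levels <- c("county", "township", "village")
  zones$level <- as.character(zones$level)
  if (!all(zones$level %in% levels)) stop("unknown hierarchy level")
  for (lv in levels) {
    ids <- zones$zone_id[zones$level == lv]
    if (length(ids) == 0L) stop("hierarchy level '", lv, "' is empty")
    if (anyDuplicated(ids)) stop("duplicate zone_id at level '", lv, "'")
    polys <- polygons[[lv]]
    if (is.null(polys) || !all(as.character(ids) %in% names(polys)))
      stop("missing polygon(s) at level '", lv, "'")
  }
  for (i in 2:3) {
    child <- zones[zones$level == levels[i], ]
    parent_ids <- zones$zone_id[zones$level == levels[i - 1L]]
    if (any(is.na(child$parent_id)) || !all(child$parent_id %in% parent_ids))
      stop("every ", levels[i], " must have exactly one ", levels[i - 1L],
           " parent")
  }
  structure(list(levels = levels, zones = zones, polygons = polygons),
            class = "admin_hierarchy")
}

#' @export
print.admin_hierarchy <- function(x, ...) {
  n <- table(factor(x$zones$level, levels = x$levels))
  cat(sprintf("<admin_hierarchy> %d counties / %d townships / %d villages\n",
              n[["county"]], n[["township"]], n[["village"]]))
  invisible(x)
}

#' Map child zone ids to their parent ids at the next level up
#' @param hier An `admin_hierarchy`.
#' @param level Child level ("township" or "village").
#' @return Named integer vector: names are child zone ids, values parent ids.
#' @export
parent_map <- function(hier, level) {
  z <- hier$zones[hier$zones$level == level, ]
  stats::setNames(as.integer(z$parent_id), as.character(z$zone_id))
}

#' Rasterize the hierarchy onto a grid, one zone raster per level
#'
#' A pixel is assigned to the zone whose polygon contains its cell center
#' (boundary inclusive); when a center lies on a shared edge the tie is
#' broken deterministically in ascending `zone_id` order. Pixels covered by
#' no polygon become `NA`.
#'
#' @param hier An `admin_hierarchy`.
#' @param spec Target `grid_spec`.
#' @return Named list of integer-valued `es_raster` zone layers, one per
#'   level (`county`, `township`, `village`).
#' @export
rasterize_hierarchy <- function(hier, spec) {
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = spec$n_rows)       # column-major over the matrix
  py <- rep(cc$y, times = spec$n_cols)
  out <- list()
  for (lv in hier$levels) {
    ids <- sort(hier$zones$zone_id[hier$zones$level == lv])
    z <- rep(NA_real_, length(px))
    for (id in ids) {
      ring <- hier$polygons[[lv]][[as.character(id)]]
      unset <- is.na(z)
      if (!any(unset)) break
      inside <- pracma::inpolygon(px[unset], py[unset],
                                  ring[, 1], ring[, 2], boundary = TRUE)
      z[which(unset)[inside]] <- id
    }
    out[[lv]] <- es_raster(matrix(z, spec$n_rows, spec$n_cols),
                           spec, units = "zone_id")
  }
  out
}

#' Regroup a zone raster by parent ids
#'
#' Replaces each child zone id with its parent id; used to check that the
#' village raster grouped by parents reproduces the township raster.
#' @param zone_raster Integer `es_raster` of child zone ids.
#' @param pmap Output of [parent_map()].
#' @return Integer `es_raster` of parent ids.
#' @export
regroup_zones <- function(zone_raster, pmap) {
  v <- zone_raster$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok] <- pmap[as.character(v[ok])]
  wrap_raster(out, zone_raster)
}

#' Write / read an admin hierarchy as GeoJSON
#'
#' One FeatureCollection; each feature is a Polygon with `level`, `zone_id`
#' and `parent_id` properties. Coordinates are projected metres.
#' @param hier An `admin_hierarchy`.
#' @param path Output `.geojson` path.
#' @export
write_hierarchy_geojson <- function(hier, path) {
  feats <- list()
  for (lv in hier$levels) {
    z <- hier$zones[hier$zones$level == lv, ]
    for (i in seq_len(nrow(z))) {
      ring <- hier$polygons[[lv]][[as.character(z$zone_id[i])]]
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      coords <- lapply(seq_len(nrow(ring)),
                       function(j) c(ring[j, 1], ring[j, 2]))
      props <- list(level = lv, zone_id = z$zone_id[i])
      if (!is.na(z$parent_id[i])) props$parent_id <- z$parent_id[i]
      feats[[length(feats) + 1L]] <- list(
        type = "Feature", properties = props,
        geometry = list(type = "Polygon", coordinates = list(coords)))
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hierarchy_geojson
#' @export
read_hierarchy_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  zones <- data.frame(level = character(), zone_id = integer(),
                      parent_id = integer())
  polygons <- list(county = list(), township = list(), village = list())
  for (f in fc$features) {
    p <- f$properties
    pid <- if (is.null(p$parent_id) || length(p$parent_id) == 0)
      NA_integer_ else as.integer(p$parent_id)
    zones <- rbind(zones, data.frame(level = p$level,
                                     zone_id = as.integer(p$zone_id),
                                     parent_id = pid))
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(xy) as.numeric(unlist(xy))))
    polygons[[p$level]][[as.character(p$zone_id)]] <- ring
  }
  admin_hierarchy(zones, polygons)
}
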