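#' Zonal aggregation of a raster over a zone raster
#'
#' Nodata pixels are excluded; a zone whose pixels are all nodata is an
#' error. Sum aggregation is additive across nested hierarchy levels.
#'
#' @param raster `es_raster` of values.
#' @param zone_raster Integer `es_raster` of zone ids.
#' @param method `"sum"` or `"mean"`.
#' @return Data frame with `zone_id`, `value`, `n_pixels`.
#' @export
zonal_aggregate <- function(raster, zone_raster, method = c("sum", "mean")) {
  method <- match.arg(method)
  check_coregistered(raster, zone_raster)
  v <- raster$values; z <- zone_raster$values
  zones <- sort(unique(z[!is.na(z)]))
  ok <- !is.na(z) & !is.na(v)
  empty <- setdiff(zones, unique(z[ok]))
  if (length(empty))
    stop("zone(s) with no data pixels: ", paste(empty, collapse = ", "))
  zf <- factor(z[ok], levels = zones)
  agg <- if (method == "sum") tapply(v[ok], zf, sum) else tapply(v[ok], zf, mean)
  data.frame(zone_id = as.integer(zones), value = as.numeric(agg),
             n_pixels = as.integer(table(zf)))
}

#' Ecological supply-demand ratio across the zones of one scale
#'
#' ESDR = (S - D) / ((Smax + Dmax) / 2), with Smax and Dmax the maxima of
#' supply and demand over the zones of the scale. Positive values are
#' surplus, negative deficit, near zero balance. For nonnegative S and D the
#' ratio is bounded in [-2, 2] and its sign equals sign(S - D); it is
#' invariant to a common positive rescaling of all S and D.
#'
#' @param S,D Numeric vectors of aggregated supply and demand per zone.
#' @return Numeric vector of ESDR values.
#' @export
esdr <- function(S, D) {
  stopifnot(length(S) == length(D))
  smax <- max(S); dmax <- max(D)
  if (smax + dmax <= 0) stop("Smax + Dmax is zero; ESDR undefined")
  (S - D) / ((smax + dmax) / 2)
}

#' Min-max normalization
#'
#' x_new = (x - xmin) / (xmax - xmin), order preserving, endpoints at 0 and
#' 1. `to = "symmetric"` additionally rescales to [-1, 1] (2*x_new - 1) for
#' workflows that state a symmetric target range.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @param to `"unit"` (default, [0, 1]) or `"symmetric"` ([-1, 1]).
#' @return Normalized numeric vector.
#' @export
minmax_normalize <- function(x, to = c("unit", "symmetric")) {
  to <- match.arg(to)
  ok <- is.finite(x)
  lo <- min(x[ok]); hi <- max(x[ok])
  if (hi - lo <= 0) stop("constant input: min-max normalization undefined")
  out <- (x - lo) / (hi - lo)
  if (to == "symmetric") out <- 2 * out - 1
  out
}

# Aggregation rule and unit conversion per service: extensive services are
# summed in a common physical unit for supply and demand; dimensionless
# indices are averaged.
service_aggregation <- function() {
  data.frame(
    service = c("CP", "WR", "PR", "FM", "HM", "LR"),
    method  = c("sum", "sum", "sum", "mean", "mean", "mean"),
    stringsAsFactors = FALSE)
}

#' Per-zone supply/demand budget tables with ESDR at each scale
#'
#' Aggregates the twelve service rasters over the county, township and
#' village zone rasters and computes the per-zone ESDR for each service from
#' that scale's own Smax/Dmax. Extensive services are summed (CP in t, WR in
#' m3 — supply converted from mm via the cell area — PR in g, demand
#' converted from ug); the dimensionless indices FM, HM, LR are averaged.
#' The aggregation method is recorded per service in the output attributes.
#'
#' @param services Output of [quantify_services()].
#' @param zone_rasters Output of [rasterize_hierarchy()].
#' @param hier The `admin_hierarchy` (for parent ids in the output).
#' @param balance_band Half-width of the |ESDR| band labelled "balance"
#'   (default 0.1).
#' @return Named list (county, township, village) of data frames with
#'   zone_id, parent_id and `<service>_{S,D,esdr,state}` columns; attribute
#'   `aggregation` records the method per service.
#' @export
build_budget_tables <- function(services, zone_rasters, hier,
                                balance_band = 0.1) {
  rules <- service_aggregation()
  out <- list()
  for (lv in names(zone_rasters)) {
    zr <- zone_rasters[[lv]]
    tab <- NULL
    for (i in seq_len(nrow(rules))) {
      svc <- rules$service[i]
      sup <- convert_budget_units(services[[svc]]$supply, svc, "supply")
      dem <- convert_budget_units(services[[svc]]$demand, svc, "demand")
      s_agg <- zonal_aggregate(sup, zr, rules$method[i])
      d_agg <- zonal_aggregate(dem, zr, rules$method[i])
      r <- esdr(s_agg$value, d_agg$value)
      block <- data.frame(zone_id = s_agg$zone_id, S = s_agg$value,
                          D = d_agg$value, esdr = r,
                          state = ifelse(abs(r) <= balance_band, "balance",
                                         ifelse(r > 0, "surplus", "deficit")))
      names(block)[-1] <- paste0(svc, "_", names(block)[-1])
      tab <- if (is.null(tab)) block else merge(tab, block, by = "zone_id")
    }
    zmeta <- hier$zones[hier$zones$level == lv, c("zone_id", "parent_id")]
    tab <- merge(zmeta, tab, by = "zone_id")
    tab <- tab[order(tab$zone_id), ]
    rownames(tab) <- NULL
    attr(tab, "scale") <- lv
    attr(tab, "aggregation") <- stats::setNames(rules$method, rules$service)
    attr(tab, "balance_band") <- balance_band
    out[[lv]] <- tab
  }
  out
}

# Supply and demand of each service enter the ESDR in one common unit:
# CP t, WR m3 (supply raster is in mm), PR g (demand raster is in ug),
# FM/HM/LR dimensionless.
convert_budget_units <- function(layer, service, side) {
  if (service == "WR" && side == "supply")
    return(wrap_raster(layer$values * cell_area(layer$spec) / 1000, layer,
                       units = "m3/pixel"))
  if (service == "PR" && side == "demand")
    return(wrap_raster(layer$values / 1e6, layer, units = "g/pixel/yr"))
  layer
}

#' Extract the zones x services ESDR matrix from a budget table
#' @param budget_table One element of [build_budget_tables()] output.
#' @return Numeric matrix (zones x 6) with zone ids as row names.
#' @export
esdr_matrix <- function(budget_table) {
  svcs <- service_aggregation()$service
  m <- as.matrix(budget_table[, paste0(svcs, "_esdr")])
  colnames(m) <- svcs
  rownames(m) <- budget_table$zone_id
  m
}
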