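#' Flood-mitigation supply via the SCS curve-number method
#'
#' Potential retention I = 25400 / CN - 254 (mm); storm runoff
#' Rp = (P - 0.2 I)^2 / (P + 0.8 I) when P > 0.2 I, else 0; supply
#' FM = 1 - Rp / P in [0, 1]. CN = 100 retains nothing (FM = 0); CN = 0
#' (water) is the infinite-retention limit and yields FM = 1.
#'
#' @param lulc LULC `es_raster`.
#' @param hsg Hydrologic-soil-group `es_raster` coded 1 = A ... 4 = D.
#' @param params A [flood_params()]; `cn_table` must cover every LULC code
#'   present.
#' @return Supply `es_raster`, dimensionless in [0, 1].
#' @export
flood_supply <- function(lulc, hsg, params = flood_params()) {
  check_coregistered(lulc, hsg)
  lu <- lulc$values; sg <- hsg$values
  codes <- sort(unique(lu[!is.na(lu)]))
  if (!all(as.character(codes) %in% rownames(params$cn_table)))
    stop("LULC code(s) missing from the CN table: ",
         paste(setdiff(as.character(codes), rownames(params$cn_table)),
               collapse = ", "))
  if (any(!sg[!is.na(sg)] %in% 1:4)) stop("HSG codes must be 1 (A) .. 4 (D)")
  cn <- matrix(NA_real_, nrow(lu), ncol(lu))
  ok <- !is.na(lu) & !is.na(sg)
  cn[ok] <- params$cn_table[cbind(match(as.character(lu[ok]),
                                        rownames(params$cn_table)), sg[ok])]
  wrap_raster(curve_number_fm(cn, params$design_storm), lulc, units = "1")
}

# Vectorized CN -> FM kernel (shared with the synthetic planting checks).
curve_number_fm <- function(cn, storm) {
  fm <- rep(NA_real_, length(cn))
  dim(fm) <- dim(cn)
  zero <- !is.na(cn) & cn == 0
  fm[zero] <- 1                       # infinite retention limit
  pos <- !is.na(cn) & cn > 0
  I <- 25400 / cn[pos] - 254
  rp <- ifelse(storm > 0.2 * I,
               (storm - 0.2 * I)^2 / (storm + 0.8 * I), 0)
  fm[pos] <- 1 - rp / storm
  fm
}

#' Flood-mitigation demand: flood-risk social-demand index
#'
#' Population vulnerability PVI = minmax(alpha*Pop + beta*Old + gamma*Child);
#' economic vulnerability EVI = minmax(per-pixel economic score), the score
#' being the developed-density class score (from the impervious fraction) on
#' built-up pixels and the per-LULC score elsewhere; demand
#' FRSD = minmax(a*PVI + b*EVI), all in [0, 1]. A spatially constant field is
#' degenerate for min-max scaling and is returned as all zeros with a warning.
#'
#' @param population,elderly,children Density `es_raster`s (>= 0).
#' @param impervious Impervious-surface fraction `es_raster` in [0, 1].
#' @param lulc LULC `es_raster`.
#' @param params A [flood_params()].
#' @return Demand `es_raster` in [0, 1].
#' @export
flood_demand <- function(population, elderly, children, impervious, lulc,
                         params = flood_params()) {
  check_coregistered(population, elderly, children, impervious, lulc)
  for (l in list(population, elderly, children))
    if (any(l$values[!is.na(l$values)] < 0)) stop("negative density")
  isa <- impervious$values
  if (any(isa[!is.na(isa)] < 0 | isa[!is.na(isa)] > 1))
    stop("impervious fraction outside [0, 1]")
  pvi_raw <- params$alpha * population$values +
    params$beta * elderly$values + params$gamma * children$values
  pvi <- minmax_matrix(pvi_raw, "population vulnerability")
  evi <- minmax_matrix(economic_score(lulc$values, isa, params),
                       "economic vulnerability")
  frsd <- minmax_matrix(params$a * pvi + params$b * evi, "flood demand")
  wrap_raster(frsd, population, units = "1")
}

#' Per-pixel economic vulnerability score
#'
#' Built-up pixels are scored by impervious-density class (open / low /
#' moderate / high at 20/50/80% thresholds); other classes take their fixed
#' LULC score (forest and water 1, grassland 2, cultivated 3, unused 4).
#'
#' @param lulc LULC code matrix.
#' @param isa Impervious-fraction matrix in [0, 1].
#' @param params A [flood_params()].
#' @return Numeric matrix of scores.
#' @export
economic_score <- function(lulc, isa, params = flood_params()) {
  score <- matrix(NA_real_, nrow(lulc), ncol(lulc))
  dev <- !is.na(lulc) & lulc == lulc_codes()[["builtup"]]
  s <- params$developed_scores
  score[dev] <- ifelse(isa[dev] > 0.8, s[["high"]],
                ifelse(isa[dev] > 0.5, s[["moderate"]],
                ifelse(isa[dev] > 0.2, s[["low"]], s[["open"]])))
  for (code in names(params$lulc_scores)) {
    m <- !is.na(lulc) & lulc == as.integer(code)
    score[m] <- params$lulc_scores[[code]]
  }
  score
}

# Min-max a matrix to [0, 1]; a constant field has no spatial contrast to
# normalize, so it degenerates to all zeros (with a warning).
minmax_matrix <- function(m, what = "field") {
  ok <- !is.na(m)
  if (!any(ok)) return(m)
  lo <- min(m[ok]); hi <- max(m[ok])
  if (hi - lo <= 0) {
    warning("constant ", what, " field: min-max normalization degenerates to 0")
    m[ok] <- 0
    return(m)
  }
  m[ok] <- (m[ok] - lo) / (hi - lo)
  m
}
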