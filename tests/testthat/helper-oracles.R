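# Independent scalar reference implementations of the per-pixel formulas,
# written as plain arithmetic (no shared code with the package internals).
# Used to check vectorized raster operations on random parameter draws.

ref_vci <- function(ndvi, ndvi_min, ndvi_max) {
  (ndvi - ndvi_min) / (ndvi_max - ndvi_min)
}

ref_crop_alloc <- function(vci_i, vci_sum, gps) gps * vci_i / vci_sum

ref_crop_demand <- function(pop, ca) pop * ca

ref_water_yield_veg <- function(p, et0, kc, awc, z) {
  r <- kc * et0 / p
  w <- z * awc / p + 1.25
  aet_ratio <- (1 + w * r) / (1 + w * r + 1 / r)
  (1 - aet_ratio) * p
}

ref_water_yield_nonveg <- function(p, et0, kc) p - min(kc * et0, p)

ref_runoff <- function(p, cj) p * cj

ref_pm25_flux <- function(vd, ch) vd * ch * 3600 / 1e6

ref_pm25_supply <- function(vd, ch, lai, area, t_hours, resusp, days) {
  f <- ref_pm25_flux(vd, ch)
  days * f * (area * lai) * t_hours * (1 - resusp)
}

ref_pm25_demand <- function(ca, permitted, h, area) {
  if (ca > permitted) (ca - permitted) * h * area * 365 * 24 else 0
}

ref_scs_fm <- function(cn, p) {
  if (cn == 0) return(1)
  i <- 25400 / cn - 254
  rp <- if (p > 0.2 * i) (p - 0.2 * i)^2 / (p + 0.8 * i) else 0
  1 - rp / p
}

ref_cc <- function(shade, kc, et0, etmax, albedo) {
  eti <- min(max(kc * et0 / etmax, 0), 1)
  0.6 * shade + 0.2 * eti + 0.2 * albedo
}

# direct double-loop CCpark for a small grid (cc, g matrices)
ref_ccpark <- function(cc, g, cell, dcool, i, j) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(cc))) for (c in seq_len(ncol(cc))) {
    d <- cell * sqrt((r - i)^2 + (c - j)^2)
    if (d <= dcool && g[r, c] == 1) {
      w <- exp(-d / dcool)
      num <- num + w * cc[r, c]
      den <- den + w
    }
  }
  if (den == 0) NA_real_ else num / den
}

ref_recreation_demand <- function(dens, per_capita) dens * per_capita

# brute-force q: explicit residual sums of squares around stratum means
ref_q <- function(y, strata) {
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (s in unique(strata)) {
    g <- y[strata == s]
    ssw <- ssw + sum((g - mean(g))^2)
  }
  1 - ssw / sst
}

ref_esdr <- function(s, d, smax, dmax) (s - d) / ((smax + dmax) / 2)
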