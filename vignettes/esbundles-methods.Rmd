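---
title: "Methods: supply-demand budgets, bundles and their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supply-demand budgets, bundles and their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esbundles)
```

`esbundles` implements a multiscale supply-demand budget analysis for six
urban ecosystem services on a common 30 m raster grid: crop production (CP),
water retention (WR), PM2.5 reduction (PR), flood mitigation (FM), heat
mitigation (HM) and landscape recreation (LR). Budgets are aggregated over a
nested county > township > village hierarchy, expressed as an ecological
supply-demand ratio (ESDR), clustered into budget bundles with k-means, and
attributed to candidate drivers with the Geodetector factor-detector
q-statistic. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic landscape generator does and does
not emulate.

## Service models

All per-pixel operations take `es_raster` layers co-registered on one
`grid_spec` (square cells, default 30 m, so pixel area $A = 900\,\mathrm{m}^2$).
`NA` marks nodata and never enters arithmetic.

### Crop production

Supply distributes a regional production total $GP_s$ (t) over cultivated
pixels in proportion to the Vegetation Condition Index,
$VCI_i = (NDVI_i - NDVI_{\min})/(NDVI_{\max} - NDVI_{\min})$, the min-max
taken over cultivated pixels only:
$CP_i = GP_s \cdot VCI_i / \sum_i VCI_i$. The allocation conserves $GP_s$
exactly. Demand is $D_{c,i} = P_{c,i} \cdot C_a$ with per-capita annual
consumption $C_a = 0.1221$ t/person.

### Water retention

Supply is water yield minus surface runoff. Yield follows the Budyko
framework: with dryness index $R = K_c \cdot ET_0 / P$ and shape parameter
$w$, $AET/P = (1 + wR)/(1 + wR + 1/R)$ and $Y = (1 - AET/P)\,P$. The
literature the model family descends from treats $w$ as a non-physical
climate-soil parameter; we use the standard plant-available-water form
$w = Z \cdot AWC / P + 1.25$ with $Z = 5$ by default, and also accept a
direct $w$ raster. On non-vegetated classes (water, built-up, unused) the
Budyko curve is undefined; there $AET = \min(K_c ET_0, P)$, the accepted
convention for those classes. Runoff is $P \cdot C_j$ with the per-class
coefficient $C_j$ (cultivated 0.347, forest 0.0267, grassland 0.0937, water
0, built-up and unused 1). Sealed classes can give negative retention
($Y < P C_j$); negatives propagate unless `clamp_negative` is set, because
the model itself says nothing about the case and hiding it would bias zonal
sums. Demand sums domestic use ($W_c$ per person, default 60 m³/yr) and the
subdistrict table's agricultural, industrial and ecological totals spread
uniformly over each subdistrict's cultivated, built-up and forest+grassland
pixels. "Industrial land" is not one of the six classes, so industrial use
falls on built-up pixels (optionally restricted by a mask); each component
conserves its table total exactly, and a nonzero total with no eligible
pixels is an error naming the subdistrict.

### PM2.5 reduction

Supply is annual dry deposition on forest canopy: flux
$F = V_d \cdot C_h \cdot 3600/10^6$ (g m⁻² h⁻¹) with deposition velocity
$V_d = 9\times10^{-4}$ m/s, canopy area $TCLA = A \cdot LAI$, daily capture
$Q_d = F \cdot TCLA \cdot T (1 - R)$ with $T = 24$ h and resuspension
$R = 0.03$, and $Q_y = D \cdot Q_d$ over $D$ non-rainy days (default 245, a
config scalar because only annual inputs exist — no daily weather pathway).
Only annual mean concentration is available, so the hourly $C_h$ is taken
equal to the annual mean raster. Demand is the annual pollutant mass above
the permitted level in the boundary-layer column over the pixel:
$(C_a - 10)\,H \cdot A \cdot 365 \cdot 24$ µg where $C_a$ exceeds the
10 µg/m³ guideline (boundary-layer height $H = 200$ m), else zero.

### Flood mitigation

Supply uses the SCS curve-number method: potential retention
$I = 25400/CN - 254$ mm, storm runoff
$R_p = (P - 0.2I)^2/(P + 0.8I)$ when $P > 0.2I$ (else 0), and
$FM = 1 - R_p/P \in [0, 1]$ for a design storm $P$ (unstated by the model's
sources at this scale; configurable, default 100 mm). $CN = 100$ converts
all rainfall to runoff ($FM = 0$); the coefficient table assigns water
$CN = 0$, which makes $I$ singular — we treat it as the $I \to \infty$
limit, i.e. full retention, $FM = 1$. Demand is a flood-risk social-demand
index: population vulnerability
$PVI = \mathrm{minmax}(\tfrac13 Pop + \tfrac13 Old + \tfrac13 Child)$,
economic vulnerability $EVI = \mathrm{minmax}(\text{economic score})$ where
built-up pixels score 5–8 by impervious-density class (breaks at 20/50/80 %)
and other classes take fixed scores (forest/water 1, grassland 2,
cultivated 3, unused 4), and $FRSD = \mathrm{minmax}(\tfrac12 PVI +
\tfrac12 EVI)$. The economic score enters per pixel (the printed sum over an
index $n$ collapses to the single pixel score). All min-max normalizations
are taken over the full grid, not per zone, to keep one reference frame.

### Heat mitigation

Cooling capacity combines shade, an evapotranspiration index
$ETI = K_c ET_0 / ET_{\max}$ (clipped to $[0,1]$) and albedo:
$CC = 0.6\,shade + 0.2\,ETI + 0.2\,albedo$. Green space cools its
surroundings: $CC_{park}$ at a pixel is the mean of $CC$ over green pixels
($g = 1$) within `dcool`, weighted by $e^{-d/d_{cool}}$ and normalized to
sum 1. The printed form of the park term carries no weight normalization
and indexes the green flag ambiguously; without normalization the quantity
is unbounded and cannot be compared with $CC \in [0,1]$, so we use the
contributing pixel's green flag and normalized weights. A pixel keeps its
own $CC$ when it belongs to a connected green patch (4-neighbour adjacency)
of at least `large_green_area`, when $CC \ge CC_{park}$, or when no green
pixel lies within `dcool`; otherwise it takes $CC_{park}$. `dcool` (450 m)
and the patch threshold (20 000 m²) follow the model family's customary
defaults and are exposed in the configuration. Demand is urban-heat-island
intensity: the excess of land-surface temperature over the mean LST of
cultivated pixels, then min-max normalized. The printed piecewise form
makes demand positive where pixels are *cooler* than cropland — the
opposite of a heat-island intensity — so the default `"intended"` mode
uses $\max(0, T_i - \bar T_c)$; the literal `"printed"` mode is retained
for fidelity.

### Landscape recreation

Supply is the green (forest + grassland) share of each subdistrict's area,
broadcast to its pixels; demand is population density (persons/m²) times
the planned per-capita green area of 13 m²/person.

## Budgets, bundles, drivers

**ESDR.** Supply and demand are first aggregated to zones — extensive
services by sum in one physical unit per service (CP in t, WR in m³, PR in
g; the WR supply raster is mm and converts via the cell area, the PR demand
raster µg), dimensionless indices (FM, HM, LR) by mean — and the ratio is
computed at zone level from the aggregates:
$ESDR = (S - D) \big/ \tfrac12 (S_{\max} + D_{\max})$, with the maxima taken
over the zones of each scale separately. Computing ESDR from zonal
aggregates (not as an average of pixel ratios) matches mapping budgets per
administrative unit, and per-scale maxima preserve the scale dependence of
budgets. For nonnegative aggregates the ratio lies in $[-2, 2]$, its sign
equals $\mathrm{sign}(S - D)$, and it is invariant to a common rescaling of
all $S$ and $D$ at a scale. Zones are labelled surplus/deficit/balance with
a configurable balance band ($|ESDR| \le 0.1$ by default; the source
notion is only "close to 0").

**Bundles.** Each service's ESDR column is min-max normalized to $[0, 1]$
(the formula's range; an optional symmetric rescale to $[-1, 1]$ exists for
workflows that state that target range) and zones are clustered by k-means
(`stats::kmeans`, Euclidean, best of 25 restarts, fixed seed). Each scale is
clustered independently. k defaults to 6 with elbow diagnostics (largest
perpendicular distance to the WSS chord) always emitted — the pipeline
never silently overrides a configured k, but it caps k at the zone count
when a scale has fewer zones (the default synthetic hierarchy has only 4
counties) and records the cap. Labels are renumbered by descending bundle
area share so numbering is reproducible, and bundle profiles are Z-scores
of bundle means across bundles (0 = average bundle; positive = above
average for that service).

**Drivers.** Zonal means of 14 candidate drivers (GDP, POP, IS, NIS, PRE,
TEM, WS, SR, SAND, SILT, CLAY, DEM, SLOPE, GR) are discretized into L = 5
quantile strata (configurable; ties merge downward with a warning) and the
factor detector computes $q = 1 - \sum_h N_h \sigma_h^2 / (N \sigma^2)$
with population variances throughout — the printed ratio cancels only with
the biased estimator. Bundle labels are categorical while q needs numeric
y; the default `"label-code"` mode uses the integer label codes, which
replicates the common applied practice, and the statistically defensible
`"indicator-mean"` mode (q on each bundle's 0/1 membership, averaged) is
offered and tagged in the output. Significance uses a permutation test
(default 999 permutations, $p = (1 + \#\{q^* \ge q\})/(1 + n_{perm})$,
threshold 0.1) rather than the noncentral-F approximation of the original
software: it is assumption-free and exactly reproducible under a seed.

## The synthetic landscape generator

No real input rasters are distributed with the analysis, so the generator
emulates the whole input suite with controllable structure: a patchy
six-class LULC mosaic (class-labelled seed points, nearest-seed assignment,
exact largest-remainder seed counts so realized shares track the configured
weights; built-up seeds biased toward the urban cores), population decaying
from two urban cores over a low rural floor, elderly/child densities as
0.18/0.12 fractions of population with noise, a monotone NW-to-SE PM2.5
gradient, LST positively coupled to the impervious fraction, smooth climate
and soil fields (precipitation mean 1093 mm; softmax soil texture; HSG from
sand quartiles), DEM with western hills plus derived slope and roughness,
GDP tied to cores and imperviousness, a per-village water-use table whose
components are nonzero only where the target class exists, and a nested
admin hierarchy built by recursive rectangular splitting with jittered cut
positions (nesting is guaranteed by construction; realistic zone shapes are
not needed for any tested property). Everything derives from one seeded
generator, so a config and seed reproduce the stack bit for bit.

The default crop total scales the reference regional yield intensity
(2.09 × 10⁶ t over the 31.32 % cultivated share of a 17 700 km² region,
about 377 t per km² of cropland) by the landscape's expected cultivated
area. This keeps the landscape-level demand/supply balance of the study
region (≈ 1.49) at any grid size; an absolute total can be configured
instead, and `crop_params()` itself defaults to the absolute regional
figure.

What the generator does **not** emulate: real geography (lake shapes,
administrative boundaries), census microstructure, seasonal or daily
weather, spatially correlated measurement error, and misregistration
between layers. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure under clean
conditions, not robustness to real-data artefacts.

**Planting.** Two routes support recovery experiments.
`plant_esdr_matrix()` places zone ESDR vectors directly at k archetype
profiles plus Gaussian noise — exact in the zero-noise limit — for
controlled tests of clustering and attribution. `plant_bundles()` perturbs
the physical layers per village zone: NDVI (crop supply), population with
both a multiplicative factor and an additive in-migration term for
deficit-planted zones (a near-empty zone cannot acquire demand by scaling),
precipitation and the water-use table, LAI and PM2.5, the hydrologic soil
group, LST, and a land-conversion lever that seals green pixels in
deficit-planted zones and greens sealed ones in surplus zones (guarding
each zone's last green/built-up pixel so water-use allocation stays
feasible). Because these levers pass through nonlinear models and global
normalizations, zone vectors approach but never equal the archetypes; at
separation 3 the two-archetype end-to-end recovery is exact (ARI = 1)
across planting seeds on the 80 × 80 test landscape. An optional driver
effect shifts a named layer per zone in proportion to the archetype label;
with effect 0 labels are independent of every driver.

## Numerical choices and degenerate inputs

- Rasterization assigns a pixel to the zone containing its center
  (boundary inclusive); a center on a shared edge goes to the smallest
  zone_id. Deterministic and order-independent.
- Min-max normalization of a spatially constant field is degenerate; the
  demand indices return all zeros with a warning rather than NaN.
- Constant NDVI over the cultivated mask, zero total VCI, zero total
  variance in q, fewer distinct values than strata, and a zero
  `S_max + D_max` are errors, not silent results.
- Distance-decay park cooling uses an FFT convolution with zero padding;
  pixels with no green within `dcool` keep their own CC (the empty-kernel
  convention).
- Crop allocation conserves its total to ~1e-9 relative (floating-point
  summation); hierarchy additivity of sum-aggregated services holds to the
  same tolerance.
- Per-stage seeds are forked deterministically from the run seed and stay
  below 2³¹.

## Problem sizes

The test suite exercises a 200 × 200 (36 km²) default landscape with a
4/16/64 county/township/village hierarchy for conservation, bounds and
end-to-end determinism; an 80 × 80 landscape with 16 villages for planting
and recovery; 64-zone driver tables with 99–199 permutations and 500
null replicates for the calibration of the permutation test. These sizes
were chosen so every documented property is measurable with comfortable
margins while the whole suite stays quick to run.

## Known limitations

- The curve-number supply ignores antecedent moisture and storm duration;
  FM is flat in CN wherever the design storm is below the initial
  abstraction, so only the runoff-producing branch is strictly monotone.
- The park-cooling term uses straight-line distance on the grid, without
  barriers or anisotropy.
- Geodetector q with `"label-code"` y treats bundle codes as ordinal — the
  field's common but imperfect practice; compare with `"indicator-mean"`
  when ranking drivers matters.
- ESDR mixes physically different services after normalization; bundle
  composition depends on the chosen aggregation units (documented above)
  as in any multi-service budget analysis.
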