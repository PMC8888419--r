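---
title: "Mapping phylloxera establishment risk from soil sand and temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping phylloxera establishment risk from soil sand and temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylrisk)
```

## The problem

Grape phylloxera (*Daktulosphaira vitifoliae*) kills own-rooted *Vitis
vinifera* through root feeding. Where a wine industry grows largely on own
roots, the practical question is prospective: *if* the insect reaches a
site, how suitable is that site for it to establish and develop quickly?
Two soil variables carry most of that signal. Coarse, sandy soils are
hostile — crawlers move poorly and survive badly in them — while soil
temperature controls development rate, with an optimal band of roughly
18–27 °C at root depth in summer. phylrisk builds categorical risk maps
from exactly these two inputs and validates them against point sites.

This vignette explains the model and the numerical choices; the README
shows the code of a complete run.

## Soil sand aggregation

Soil surveys report percent sand (g sand per 100 g soil) per depth
interval. The profile aggregate over 0–100 cm is the thickness-weighted
mean

$$\bar s \;=\; \frac{\sum_i w_i\, s_i}{\sum_i w_i},
  \qquad w_i = \mathrm{bottom}_i - \mathrm{top}_i ,$$

with weights 5, 15, 30 and 50 cm for the standard intervals. The sum runs
only over intervals with data at the pixel, so the weights renormalize:
a pixel surveyed only in the top 20 cm gets a shallow-profile estimate
rather than an imputed deep value, and a pixel with no data at any depth
(bedrock, unsurveyed) stays nodata. We deliberately apply no
partial-profile penalty; absence of deep data is treated as
uninformative, not as zero sand. Remaining gaps can be filled from a
secondary survey raster (`fill_gaps()`), which wins only where the primary
is nodata. Any non-overlapping interval set is accepted, not just the
standard four.

Resampling a secondary raster onto the working grid offers nearest and
bilinear kernels. Bilinear propagates nodata conservatively — any nodata
neighbor makes the output cell nodata — because interpolating across a
survey-gap edge would fabricate soil where none was measured; filling
gaps is the explicit job of `fill_gaps()`, not a side effect of
resampling.

## Station temperature summarization

Each station's 15-minute soil-temperature series (20.32 cm depth) is
reduced to the **mean daily maximum** over a June 1 – August 31 window
(92 days per year) pooled across the study years. The daily *maximum*
rather than the mean is used because network stations typically sit over
irrigated ground that runs intermittently cool relative to vineyard
soils; the maximum is the less biased proxy for what vine roots
experience. Pooling across years with no per-year balancing means a
station missing one summer simply contributes fewer days.

Quality control is deliberately simple and configurable: a station-day
enters only with at least `min_records_per_day` readings (default 48,
half of the 96 a complete day yields — enough to make the observed
maximum a fair estimate of the true one without discarding mildly gappy
days), rows with unparseable timestamps or non-numeric temperatures are
dropped and counted, and stations with zero retained days are excluded
rather than imputed. Timestamps are taken at face value with day
boundaries at local midnight; the 15-minute cadence makes sub-hour
timezone subtleties immaterial for a daily maximum.

## Ordinary kriging

Station scalars are interpolated by ordinary kriging, authored in the
package rather than delegated, since no geostatistics library is among
its dependencies. The empirical semivariogram

$$\hat\gamma(h) = \frac{1}{2N(h)} \sum_{d_{ij}\in \mathrm{bin}(h)}
  (z_i - z_j)^2$$

uses 12 equal-width bins up to half the maximum pairwise distance by
default — the conventional cutoff beyond which bins hold few,
geometry-driven pairs. A spherical model (default; exponential and
gaussian available) is fitted by pair-count-weighted least squares.
Because the model is linear in nugget and partial sill once the range is
fixed, the fit scans a fixed logarithmic grid of 40 candidate ranges,
solves the 2-parameter weighted problem in closed form at each (with
non-negativity handled at the boundary), and polishes the best candidate
with L-BFGS-B under bounds. There is no randomness anywhere in the fit,
so refits are bit-reproducible.

Prediction solves the augmented system

$$\begin{pmatrix} \Gamma & \mathbf 1 \\ \mathbf 1^\top & 0 \end{pmatrix}
  \begin{pmatrix} \mathbf w \\ \mu \end{pmatrix} =
  \begin{pmatrix} \boldsymbol\gamma_0 \\ 1 \end{pmatrix}$$

once per map, factoring the left-hand side a single time and solving for
all cell centers as simultaneous right-hand sides (global kriging; with a
couple hundred stations there is no need for search neighborhoods, and
their absence avoids discontinuity artifacts). Weights sum to one by
construction, predictions are exact at stations when the nugget is zero,
and the kriging variance is clamped at zero against roundoff. Stations
closer together than one cell are averaged into one point first to
protect the system from near-singularity; a genuinely singular system
(e.g. a degenerate all-zero variogram) raises a named error rather than
returning garbage. `krige_loo()` provides a leave-one-out report for
manual model comparison; automatic model selection is out of scope.

## Classification and combination

Thresholds follow the literature values and are configurable: sand `<65`
HIGH, `65–80` MODERATE, `>80` LOW; temperature `18–27` HIGH (inclusive),
otherwise LOW. Boundary membership is fixed by how the break points are
written — strict inequalities bound the outer sand classes, so 65 and 80
belong to MODERATE; the temperature band is written as a closed interval,
so 18 and 27 are HIGH. The combined map is a modification of the sand map
with temperature as a one-notch modifier (sand dominance):

| sand | temperature | combined |
|------|-------------|----------|
| LOW | any | LOW |
| MODERATE | HIGH | MODERATE |
| MODERATE | LOW | MODERATE-LOW |
| HIGH | HIGH | HIGH |
| HIGH | LOW | HIGH-MODERATE |

Pixels with nodata sand are nodata in the combined map regardless of
temperature. The reverse case — valid sand, nodata temperature — is
genuinely ambiguous (a temperature surface kriged onto the full grid has
no gaps, so the case arises only with clipped or partial inputs); the
`temp_nodata_policy` option selects between `nodata` (default,
conservative: do not report a combined class built on a missing factor)
and `passthrough_sand` (keep the unmodified sand class). Area summaries
count equal-area cells of the classified region; site validation samples
the nearest cell center, with ties broken toward the smaller row then
column index for determinism.

## Synthetic worlds and what they show

The generator builds inputs with exact ground truth: sand layers as a
shared Gaussian random field (exponential covariance
$C(h)=\sigma^2 e^{-h/L}$, dense Cholesky, capped at ~12 000 cells) plus
independent per-layer perturbations and independent nodata holes; station
series as a smooth east-west baseline trend plus a diurnal sinusoid whose
peak falls exactly on the 15-minute sampling lattice (so the noise-free
mean daily maximum is the closed form `base + amplitude`) plus white
noise; validation sites at cell centers of designed classes.
`designed_sand_layers()` swaps the stationary mean for an arbitrary
designed raster, which is how the end-to-end test builds a world with
known class geography and checks that the full pipeline recovers the
designed area fractions to within two percentage points and the designed
site labels exactly.

Default generator settings (a 40×40 grid at 14.5 m — the working
resolution of the real maps —, sand mean near 60 % with standard
deviation ≈ 11 points and a 120 m correlation length, 10 % survey gaps,
12 stations, summer baselines near 21 °C with a ±2.5 °C spatial trend, a
5 °C diurnal swing, 0.5 °C noise, two years of records, 23 sites) are
chosen once to resemble an agricultural survey region at desk scale, and
the test suite runs at these sizes. What the synthetic world does *not*
emulate: real pedology (sand is not a stationary Gaussian field),
irrigation-driven temperature regimes, instrument drift, or the true
spatial layout of any region. Passing tests therefore demonstrate that
the *machinery* — aggregation, QC, kriging, classification, tallying — is
correct and internally consistent, not that the thresholds themselves are
ecologically right; those come from the experimental literature.

## Numerical and design notes

* Grids live in one projected, meter-unit CRS; the package never
  reprojects and checks CRS tags for verbatim equality. ASCII rasters
  carry the tag in a `.prj` sidecar.
* Nodata is held as `NA` in memory; sentinels exist only in files, so a
  sentinel value can never masquerade as data.
* The GeoTIFF codec is intentionally minimal (single-band, uncompressed,
  both byte orders, int/float depths) and raises named errors on
  anything else — multi-band or compressed inputs should be exported to
  a supported form upstream.
* Point-in-polygon clipping uses even-odd ray casting over all rings, so
  holes and multi-part polygons need no winding-order bookkeeping.
* Variogram fitting weights bins by pair count; with fewer than three
  non-empty bins the fit refuses rather than extrapolating.
* All simulation randomness flows from explicit seeds through an
  RNG-state-preserving wrapper; reruns are byte-identical, which the
  pipeline tests assert on the categorical rasters.

## Limitations

Soil moisture and atmospheric humidity, both plausibly relevant to
phylloxera performance, are not modeled; nor are weighting schemes that
blend the two factors continuously — the combination is an ordinal
matrix. Kriging is isotropic and global; strongly anisotropic temperature
fields would need an anisotropy extension. The dense Gaussian-field
generator is quadratic in cell count and capped accordingly; larger
synthetic worlds would need circulant embedding.
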