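# phylrisk

Raster-based risk mapping of grape phylloxera (*Daktulosphaira
vitifoliae*) establishment from soil sand content and summer soil
temperature.

Phylloxera is a root-feeding pest that is lethal to own-rooted *Vitis
vinifera*; vineyard regions that grow on own roots rather than resistant
rootstock need to know, before the insect arrives, which sites would let it
thrive. Two soil factors dominate that suitability: texture (coarse, sandy
soils impede the insect's movement and survival) and summer soil
temperature (development is fastest in an optimal thermal band). phylrisk
turns layered soil-survey sand rasters and a network of station
soil-temperature records into categorical risk maps, area summaries, and a
site-level validation report — the workflow a viticulture extension group
would run for a whole growing region. It is aimed at agricultural GIS
analysts and quantitative plant-pathology researchers.

## Method

1. **Soil sand.** Per-depth percent-sand rasters (0–5, 5–20, 20–50,
   50–100 cm) are merged into one 0–100 cm profile value per pixel by the
   thickness-weighted average
   `s = Σᵢ wᵢ sᵢ / Σᵢ wᵢ`, `wᵢ = bottomᵢ − topᵢ`,
   renormalized over the depths with data at each pixel; pixels with no
   data at any depth stay nodata and can be filled from a secondary survey
   raster (resampled to the working grid first).
2. **Soil temperature.** 15-minute station records at 20.32 cm depth are
   reduced to each station's *mean daily maximum* over June 1 – August 31
   across the study years (days with fewer than half of the expected 96
   readings are dropped). The station scalars are interpolated to the
   working grid by ordinary kriging: weights solve the augmented system
   `[Γ 1; 1ᵀ 0][w; μ] = [γ₀; 1]` built from a semivariogram model
   (spherical, exponential or gaussian) fitted to the empirical
   semivariogram `γ̂(h) = Σ(zᵢ−zⱼ)²/2N(h)` by pair-count-weighted least
   squares.
3. **Classification.** Sand: `<65 %` HIGH, `65–80 %` MODERATE, `>80 %`
   LOW. Temperature: `18–27 °C` HIGH, otherwise LOW. The combined
   five-class map treats sand as dominant and temperature as a modifier
   (e.g. sand-HIGH with temperature-LOW → HIGH-MODERATE; sand-LOW stays
   LOW regardless of temperature).
4. **Summaries and validation.** Equal-area cell counts give per-class
   area fractions; point sites are looked up by nearest cell center and
   tallied per class.

A synthetic-data generator (Gaussian random fields with exponential
covariance, diurnal station series, designed class geography) provides
ground-truthed inputs for end-to-end testing.

## Worked example

```r
library(phylrisk)
dir <- file.path(tempdir(), "demo")

cfg <- sim_config(seed = 42L)          # 40x40 grid @ 14.5 m, 12 stations
paths <- simulate_world(cfg, dir)      # writes rasters, records, polygon

layers <- make_soil_layers(cfg)
sand <- depth_weighted_average(layers)
sand <- fill_gaps(sand, read_raster(paths$fill))

records <- parse_station_records(paths$records)
daily <- daily_maxima(records, cfg$window)
summaries <- summarize_stations(daily, read.csv(paths$coords))

emp <- empirical_variogram(summaries$x, summaries$y, summaries$mean_daily_max_c)
vm <- fit_variogram(emp, "spherical")
vm
#> spherical variogram: nugget 0, partial sill 2.067, range 881.9 m
#>   fitted: weighted SSE 4.029 over 11 lag bins
temp <- krige_grid(summaries, vm, cfg$spec)

combined <- combine_grids(classify_grid(sand, classify_sand),
                          classify_grid(temp, classify_temp))
area_summary(combined)
#> area by risk class (fraction of classified cells):
#>   HIGH             37.2%  (596 cells)
#>   HIGH_MODERATE    33.9%  (542 cells)
#>   MODERATE         16.9%  (270 cells)
#>   MODERATE_LOW      8.7%  (139 cells)
#>   LOW               3.3%  (53 cells)
#>   nodata: 0.0% of the full extent

sites <- make_sites(combined, c(HIGH = 4, MODERATE = 2), seed = 7)
tally(assign_site_risk(combined, sites))
#> site risk tally (6 labelled sites):
#>   HIGH             4  (66.7%)
#>   ...
#>   MODERATE         2  (33.3%)
```

The variogram line reports the spatial-dependence fit behind the
temperature surface; the area summary says what share of the classified
region falls in each suitability class; the tally shows that sites planted
at cells of known class are recovered exactly.

The same analysis runs file-to-file through a YAML config
(`system.file("extdata", "config_template.yaml", package = "phylrisk")`)
with `run_stage()` / `run_pipeline()`, or from a shell via
`Rscript inst/cli/phylrisk.R run-all --config config.yaml`.

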