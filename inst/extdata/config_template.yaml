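# phylrisk pipeline configuration template.
# Relative paths resolve against this file's directory.

seed: 42

# Target raster geometry (projected CRS, meter units, square cells).
grid:
  n_rows: 40
  n_cols: 40
  x_origin: 500000.0      # west edge (m)
  y_origin: 5200000.0     # north edge (m)
  cell_size: 14.5         # m per pixel
  crs: "EPSG:32610"

# Depth-interval percent-sand rasters (ESRI ASCII or GeoTIFF) and an
# optional full-coverage gap-fill raster.
soil:
  layers:
    - {path: sand_000_005.asc, top_cm: 0,  bottom_cm: 5}
    - {path: sand_005_020.asc, top_cm: 5,  bottom_cm: 20}
    - {path: sand_020_050.asc, top_cm: 20, bottom_cm: 50}
    - {path: sand_050_100.asc, top_cm: 50, bottom_cm: 100}
  fill:
    path: sand_fill.asc
    resample_method: bilinear   # or nearest

# Station soil-temperature records (15-min cadence) and coordinates.
temperature:
  records: station_records.csv     # station_id,timestamp,soil_temp_c
  coords: station_coords.csv       # station_id,x,y
  window:
    start: [6, 1]                  # June 1
    end: [8, 31]                   # August 31
    years: [2019, 2020]
  min_records_per_day: 48          # half of the 96 expected readings

# Variogram / ordinary kriging settings.
kriging:
  family: spherical                # spherical | exponential | gaussian
  n_lags: 12
  max_dist: null                   # null = half the max pairwise distance

# Optional clipping polygon (GeoJSON Polygon/MultiPolygon, same CRS).
boundary: boundary.geojson

# Risk thresholds.
thresholds:
  sand_breaks: [65, 80]            # <65 HIGH, 65-80 MODERATE, >80 LOW
  temp_band: [18, 27]              # inside (inclusive) HIGH, outside LOW

# Combined class where temperature is nodata but sand is valid:
# nodata | passthrough_sand
temp_nodata_policy: nodata

# Validation sites (CSV with site_id,x,y[,known_label] or GeoJSON points).
sites: sites.csv

# Stage outputs are written here (relative to this file).
output_dir: out
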