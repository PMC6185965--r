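# Stylized-Europe example: 6 regions over 3 latitude bands, 60 cells,
# 30 harvest years, baseline + 2 pathway analogues x 2 climate-model
# analogues, 4 pseudo-models, both crop presets.
seed: 20260920
years: 30
crops: [winter_wheat, grain_maize]
grid:
  n_cells: 60
  regions: [north-west, north-east, central, south-west, south-east, britannia]
  lat_band: [temperate, boreal, temperate, mediterranean, mediterranean, temperate]
  mean_rainfed: 8000
  mean_irrigated: 1500
ensemble:
  n_models: 4
  canopy_capable: [true, true, true, false]
scenarios:
  rcps: [rcp45, rcp85]
  gcms: [warm-wet, hot-dry]
simulation:
  raw_fraction: 0.5
evaluation:
  trend_slope: 0.05
  noise_sd: 0.25
  alpha: 0.05
sensitivity:
  collapse_replicates: true
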