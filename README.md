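# icefloc

Quantification of macroscopic algal aggregates under Arctic sea ice from
upward-looking ROV imagery.

Buoyant algal aggregates — rounded masses of pennate diatoms and
filamentous strings of *Melosira arctica* — collect against the underside
of sea ice, where neither ice cores nor water sampling capture them. An
ROV with an upward-looking camera sees them as dark blobs against the
bright ice. `icefloc` is for sea-ice ecologists and image-analysis
developers working with such surveys: it implements the full analysis
chain and a synthetic under-ice survey generator with exact ground truth,
so every stage is testable without raw dive video.

## What it computes

Given frames (384 × 288 px, 8-bit RGB) with navigation records (depth,
tilt, altimeter distance to the ice, floe-fixed x/y):

1. **Detection** — centred 250 × 200 px crop, green-channel threshold
   (aggregate: green ∈ [0, 100] of 255), 8-connected components with
   pixel area, contour perimeter, fitted ellipse and solidity; automatic
   flagging of merged "clumps" by convex-hull solidity.
2. **Quality control** — frames deeper than 5 m or tilted above 10° are
   discarded; regions of ≤ 10 px count toward abundance/coverage only.
3. **Metric registration** — pixel pitch k·h (k = 4.5 mm px⁻¹ m⁻¹ at
   altimeter distance h); equivalent circular diameter d = 2√(A/π),
   eccentricity ε = √(1 − (minor/major)²), circularity 4πA/P²; ice draft
   = depth − altimeter.
4. **Gridding** — frame results averaged on a floe-fixed 3 × 3 m raster so
   overlapping track segments cannot dominate station statistics.
5. **Biovolume & carbon** — every aggregate as a sphere of its ECD,

   V = a · (4/3)·π·(d/2)³  [ml m⁻²],  C = 0.39 · V  [mg C m⁻²],

   evaluated under six averaging schemes (`aggregate_list`, `global_mean`,
   `global_median`, `gridded_mean`, `gridded_median`, `raster_cells`)
   whose spread measures the estimation uncertainty.
6. **Spatial statistics** — Lloyd's index of patchiness P = m*/m with mean
   crowding m* = m + (s²/m − 1); power-law size spectra f(d) = c·d^b by
   binned log–log least squares (R² < 0.8 flagged) with a restricted fit
   over d > 2 cm; eccentricity-based rounded/filamentous type fractions;
   station-level Pearson correlations.

The synthetic module generates ice scenes (draft, roughness,
transmittance), clustered aggregate fields with truncated power-law sizes
(Thomas process, optional trapping in draft minima), simulated ROV
surveys, and rendered frames — with a ground-truth table linking every
rendered aggregate instance to its generator parameters.

## Worked example

Simulate the reference scenario (a 60 × 60 m floe, one ridge keel,
clustered aggregates with slope −3 diameters of 2–25 cm at ~3 m⁻²,
surveyed on a 5 m lawnmower grid) and analyze it end to end:

```r
library(icefloc)
report <- runPipeline(referenceScenario(seed = 1))
report
#> StationReport: SYN-REF
#>   frames: 288 valid / 291 input; 970 detections; 235 occupied 3x3 m cells
#>   biovolume (ml m^-2): aggregate_list=305.76, global_mean=89.56,
#>     global_median=41.54, gridded_mean=93.52, gridded_median=63.76,
#>     raster_cells=142.88
#>   Lloyd's P = 1.36
#>   validation: recall 0.985 precision 0.997
```

Three frames failed quality control (the ROV dipped below the 5 m depth
cut while crossing the ridge keel). The six biovolume
estimates span a factor of ~7 from the same detections: `global_median`
cubes the median diameter and so discounts the heavy size tail, while
`aggregate_list` sums every individual sphere volume (and double-counts
overlap). That spread — not any single number — is the uncertainty of
areal biomass estimation from 2-D imagery. Against the rendered ground
truth, 98.5 % of visible aggregates were recovered with 99.7 % precision,
and the restricted size-spectrum fit returns a slope near the generating
−3:

```r
report@sizeFits$restricted$b
#> [1] -3.074
```

Published station summaries of the 2012 central-Arctic survey ship with
the package for comparison and consistency checks:

```r
vol <- referenceBiovolume()
v <- vol[vol$block == "volume_ml_m2", ]
biomassChange(v[["ICE-1"]], v[["ICE-9"]])   # same floe, 7 weeks apart
#> [1] 92.50 95.00 88.00 66.67 67.31 81.82    # percent loss, six methods
carbonFromVolume(10.4)                       # ICE-7 global-mean volume
#> [1] 4.056                                  # mg C m^-2 (printed as 4.0)
```

The loss range 67–95 % across methods is the basis of the published
conclusion that two thirds or more of the late-summer aggregate biomass
disappeared before freeze-up.

## Package layout

- `R/synthetic.R` — scene, aggregate field, survey and frame generators
- `R/detection.R` — threshold, labeling, region measurement, QC, clump flag
- `R/geometry.R` — metric registration and per-frame summaries
- `R/gridding.R` — 3 × 3 m floe-fixed raster averaging
- `R/biomass.R` — the six biovolume estimators and carbon conversion
- `R/spatial_stats.R` — patchiness, size spectra, type fractions, correlations
- `R/pipeline.R` — orchestration, validation harness, station comparison
- `vignettes/under-ice-aggregates.Rmd` — the methods vignette (model,
  parameter choices, validation design, limitations)
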