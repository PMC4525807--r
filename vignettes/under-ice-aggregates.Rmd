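---
title: "Quantifying under-ice algal aggregates from upward-looking imagery"
author: "icefloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying under-ice algal aggregates from upward-looking imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Macroscopic (> 1 cm) algal aggregates — rounded masses of pennate diatoms
and filamentous strings of *Melosira arctica* — float up against the
underside of Arctic sea ice, where they are invisible to ice coring and
hard to reach by divers. An ROV flying a few metres below the ice with an
upward-looking camera turns the problem into image analysis: aggregates
appear as dark blobs against the bright, translucent ice. `icefloc`
implements the full chain from raw frames to station-level ecology —
segmentation, quality control, metric registration, floe-fixed gridding,
biovolume/carbon estimation, and the spatial statistics (patchiness, size
spectra, type fractions) — together with a synthetic scene and survey
generator that provides exact ground truth for every stage.

## Detection model and its assumptions

A pixel is classified as aggregate when its green-channel value lies in
**[0, 100]** of 255 (inclusive on both ends; the bounds are configurable).
This assumes the ice background stays well above the band — true in
diffuse daylight under ice, and deliberately violated in the generator's
adversarial mode to probe false positives at dark ice transitions. Frames
are first cropped to a centred 250 x 200 px window (the native 384 x 288
frame has unreliable lighting and data overlays at the edges; the crop
position is configurable because only the output size is part of the
protocol).

Connected components use 8-connectivity by default (diagonally touching
pixels join, matching visual merging; 4-connectivity is available).
Per-region measurements:

* **area**: pixel count;
* **perimeter**: Moore-traced boundary chain, length-corrected with the
  Vossepoel–Smeulders weights (0.980 per axial step, 1.406 per diagonal,
  −0.091 per corner) plus a half-pixel dilation term of pi. On digitized
  test shapes this lands within a few percent of the continuum perimeter
  for both disks and squares, and keeps circularity `4*pi*A/P^2` at or
  below 1 up to discretization — naive boundary-pixel counts put a digital
  disk's circularity near 1.3;
* **ellipse axes and orientation** from second central moments with the
  1/12 unit-pixel variance added (a one-pixel-wide filament then reports a
  ~1 px minor axis instead of zero);
* **solidity**: area over the number of lattice points inside the convex
  hull of the pixel centres, so digitized convex shapes score ~1
  regardless of size.

Quality control mirrors the dive protocol: frames deeper than 5 m or
tilted more than 10 degrees are discarded (strict inequalities — a frame at
exactly 5 m / 10 degrees is retained, following the protocol's wording), as
are frames without navigation. Regions of more than 10 pixels are
*measurable* (full shape statistics); smaller regions still count toward
abundance and coverage. The protocol's manual screening of mis-detected
frames is replaced by two reproducible devices: an automated clump flag and
an optional frame blocklist.

**Clump flag.** Close-lying aggregates merged into one thresholded region
would masquerade as a single large aggregate and, cubed in the volume
formula, badly inflate biomass. Isolated convex aggregates measure
solidity above ~0.99 even with pixel noise, while two merged equal disks
score ~0.88 (the tangent-disk value is analytic), so the default threshold
of **0.9** separates the populations; flagged regions keep counting toward
abundance and coverage but leave all size and shape statistics. A
supplementary robust size-outlier rule (on log areas, because power-law
areas make any untempered outlier cut cull the genuine large-size tail) is
available but off by default.

## Metric registration

A pinhole camera collapses to one laboratory constant *k* = 4.5 mm per
pixel per metre of standoff, giving the nominal 4–5 mm resolution at the
typical 1 m distance to the ice. The metric scale of a frame is linear in
its altimeter reading; areas scale with its square. The image footprint is
the metric area of the analysis crop (only cropped pixels are analyzed, so
only they define the surveyed area). Ice draft is ROV depth minus
altimeter distance, clipped at zero with a counter (sensor noise can
invert the difference). Tilt below the 10 degree cut is *not* corrected
projectively — it is one of the contributors to the sub-15 % size
uncertainty budget that the validation harness checks explicitly.

Units follow the survey convention throughout: areas m^2, aggregate
lengths cm, volumes ml (= cm^3) per m^2, carbon mg C per m^2.

## Gridding

Overlapping ROV tracks (especially near the launch hole) sample some spots
many times. All frame-level results are therefore averaged onto a floe-
fixed raster of **3 x 3 m** cells — the magnitude of the positioning
uncertainty — keyed by each frame's nadir point. Cell values are arithmetic
means over frames, so duplicating a frame inside its cell changes nothing;
that invariance is the property the grid exists for and is asserted
directly in the tests. Diameter statistics are the exception: they pool
the individual aggregates of the cell's frames, because a per-frame-mean
of diameters would weight a lonely aggregate in one frame like five in
another. Cells never visited are *absent*, not zero — absence of
observation is not absence of aggregates. The grid origin defaults to the
minimum observed position and is stored with the output.

## Biovolume and carbon

Each aggregate is modelled as a compact sphere of its equivalent circular
diameter, V = a · (4/3) pi (d/2)^3, and the station estimate is computed
under six averaging schemes (`aggregate_list`, `global_mean`,
`global_median`, `gridded_mean`, `gridded_median`, `raster_cells`) whose
spread is itself the message: with heavy-tailed sizes the schemes
legitimately disagree by large factors, because E[d^3] far exceeds
(E[d])^3 and (median d)^3. Where the protocol wording leaves the averaging
ambiguous, the package fixes it as: abundance is frame-averaged (it is a
per-image quantity); diameters pool individual aggregates, globally or
within cells; the gridded station diameter is the mean over occupied cells
of the per-cell mean (or median) ECD; `raster_cells` evaluates the formula
per cell with the cell-mean ECD and averages the per-cell volumes (cells
with no measurable diameter contribute zero volume). The survey area of
`aggregate_list` is the *sum* of valid frame footprints without overlap
deduplication — deliberately reproducing that scheme's documented
overestimate. Diameters entering any size statistic are the ECDs of
measurable, unflagged detections; abundance always includes everything.
Carbon is volume times 0.39 mg C ml^-1 (390 mg C per litre, the measured
aggregate carbon density), configurable. Report tables round to one
decimal, half away from zero.

## Spatial statistics

**Lloyd's patchiness.** Mean crowding m\* = m + (s^2/m − 1) and P = m\*/m
on per-cell aggregate counts (cell mean abundance x cell area, rounded),
occupied cells only. Two variance conventions exist in the literature: the
sample variance (the package default, matching the index's common worked
examples) and the population variance, which makes m\* *exactly* the
per-individual mean number of same-cell neighbours, sum x(x−1) / sum x.
Both are exposed; the tests prove the population form equal to the
brute-force per-individual count on enumerated configurations. P is ~1 for
Poisson-dispersed counts, below 1 for even spacing, and grows with
clustering.

**Size spectra.** The number size distribution f(d) = c d^b is fitted by
least squares on log10 density versus log10 diameter over logarithmically
spaced bins (counts normalized by bin width; empty bins dropped; at least
20 diameters and 3 non-empty bins required, otherwise the fit is refused
rather than returned). This transparent binned estimator matches the
analysis era of the protocol; a truncated-power-law maximum-likelihood
mode is included for sensitivity analysis. Fits with R^2 < 0.8 are
flagged. Two fits are reported per station: the full spectrum (lower bound
three pixel pitches at the median standoff — below that, detection is
unreliable) and the restricted fit over d > 2 cm. On simulated surveys the
full fit is biased flat by edge-clipped partial detections that leak small
ECDs into the lowest bins; the restricted fit is the one compared against
the generating exponent.

**Type fractions.** Station mean eccentricity maps linearly onto the
observed extremes to give rounded/filamentous fractions. The printed form
of this mapping in the original survey report assigns the *spherical*
label to the eccentricity *maximum*, contradicting its own anchoring
statement (high eccentricity means elongation); the package default
(`"anchored"`) uses the self-consistent assignment and `"literal"`
reproduces the printed one — the two are exact mirror images and the
switch is exposed rather than guessing intent.

**Correlations.** Station-level Pearson correlations with two-sided
p-values and no multiplicity correction, matching the original analysis.

## The synthetic generator: what it emulates, what it does not

The generator exists so every stage can be tested against exact ground
truth without the original dive video. It emulates the study conditions:

* **Scene** (`genIceScene`): smooth Gaussian draft field (FFT-convolved,
  default mean 1.2 m, sd 0.25 m, correlation length ~10 m) plus
  Gaussian-profile ridge keels; roughness as windowed sample sd of draft;
  transmittance decaying exponentially with draft with melt-pond patches.
* **Aggregates** (`genAggregateField`): Thomas parent–offspring clustering
  (chosen because its overdispersion is predictable, making patchiness
  tests sharp), truncated power-law diameters (default b = −3 over
  1–30 cm), rounded/filamentous type labels with eccentricities in
  [0.30, 0.85] and [0.93, 0.995]. Trapping in under-ice depressions is
  emulated by rejection thinning with acceptance weight
  exp(−affinity · draft/tau) — the field observation is qualitative only,
  so this affinity is a stand-in, not an inference target.
* **Survey** (`simulateSurvey`): lawnmower or random-walk track at
  0.5 m s^-1, one frame per 5 s, ~1 m standoff, Gaussian depth/altimeter/
  position noise and half-normal tilt.
* **Rendering** (`renderFrame`): 8-bit 384 x 288 frames, background green
  ~200 with a linear gradient and pixel noise, aggregates as filled
  ellipses at green ~40 through the pinhole model. Clean mode keeps the
  darkest background above the 0–100 band; the adversarial mode pushes a
  corner below it to generate controlled false positives.

Not emulated: radiative transfer and realistic ice texture, lens
distortion, 3-D filament geometry (filaments are high-eccentricity
ellipses, not curvilinear strings), biological patchiness mechanisms
beyond the cluster process, and video compression artifacts. Passing the
validation harness therefore demonstrates the *pipeline's* fidelity —
segmentation, measurement, gridding, statistics — under controlled
contrast, not the detectability of faint aggregates in real footage.

## Validation design

The reference scenario (`referenceScenario()`) is a 60 x 60 m floe with
one ridge, clustered draft-attracted aggregates of 2–25 cm at a realized
abundance near 3 m^-2 (the study-wide mean), surveyed on a 5 m lawnmower
grid (~290 frames). Checks:

* detection recall and precision >= 0.95 against rendered ground truth;
* mean absolute ECD error a few percent; across standoffs 0.5–2 m and
  diameters at least three pixel pitches, every size error < 15 % (the
  stated uncertainty bound of the technique);
* measured abundance within 10 % of the true field density (a few percent
  of upward bias is inherent: aggregates partially entering the crop are
  counted, so the effective footprint slightly exceeds the crop);
* restricted slope within 0.3 of the generating exponent at survey scale,
  and within 0.3 at n = 5000 for b in {−1.5, −2.2, −3} from the sampler;
* Lloyd's P in [0.95, 1.05] on Poisson counts (10^4 cells) and > 2 on
  strongly clustered Thomas fields.

For biovolume, recovery is judged against the *same estimator evaluated on
perfectly observed frame contents* (the rendered-instance ground truth
over the same footprints and cells), not against the summed true areal
biovolume: with power-law sizes the median/mean-diameter estimators sit
far below the summed volume by construction, and finite footprints sample
large aggregates preferentially (a larger aggregate intersects more
frames) — both effects are properties of the estimators that a real survey
shares, not pipeline defects. Against the perfectly-observed baseline,
`gridded_median` and `raster_cells` agree within 25 %.

Problem sizes throughout (60 m floe, ~290 frames, n = 5000 samples,
10^4 cells) were chosen as the smallest at which these statistical checks
are sharp; all randomness funnels through a single seed per run, and a
fixed seed reproduces every artifact byte for byte.

## Known limitations

* The green-band threshold has no learning component; dark ice features at
  type transitions become false positives exactly as in the field protocol
  (the adversarial rendering mode exists to measure this).
* The clump flag is a solidity heuristic; a genuinely convex union of two
  overlapping aggregates passes it.
* Published station-level absolute values cannot be recomputed from the
  shipped summary tables (per-image data do not survive into the printed
  summaries; the printed abundance and mean diameter of the richest
  station give a volume an order of magnitude above its printed estimate),
  so the in-table checks are internal-consistency checks: carbon/volume
  ratio, row means, resampling loss percentages, the coverage extremum,
  and the station correlations.
* Lloyd's index on *occupied* cells only: vast empty stretches outside the
  track do not enter, so P is conditional on the surveyed area.

```{r example}
library(icefloc)
report <- runPipeline(referenceScenario(seed = 1))
report
biovolumeTable(report)
```
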