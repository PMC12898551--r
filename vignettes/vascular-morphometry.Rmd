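---
title: "Depth-resolved vascular morphometry for photoacoustic breast volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved vascular morphometry for photoacoustic breast volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After total breast reconstruction with autologous fat grafting (AFG), graft
survival depends on revascularisation from the recipient bed. Photoacoustic
imaging (PAI) produces label-free 3D maps of hemoglobin-rich structures, so
vascular changes in the grafted breast can be followed non-invasively against
the non-operated (contralateral) breast as a within-patient control. The
quantitative questions are three:

1. **Depth-stratified vascular density.** Within periareolar 3 × 3 cm ROIs,
   what fraction of the image is vessel signal in each 2.5 mm depth layer
   from the skin surface (eight layers, 0–20 mm), after grayscale conversion
   and binarisation at a fixed threshold of 75? The superficial layer
   (0–2.5 mm) is where graft revascularisation from the cutaneous plexus
   shows up: reconstructed sides run near 28%, contralateral sides near 20%.
2. **Vessel-caliber distribution.** Vessel diameters measured within the
   ROIs, classified as small / medium / large against cutoffs of 0.3 and
   0.5 mm — the pooled contralateral quartiles (Q1 0.29, median 0.37,
   Q3 0.50 mm) rounded to one decimal. Diameters exactly at a cutoff are
   medium.
3. **Remodeling trends.** The side difference (reconstructed minus
   contralateral) of each class proportion, plotted against the
   postoperative interval and summarised by an ordinary least-squares trend
   line. Vascular remodeling predicts a rising small-vessel difference and a
   falling large-vessel difference; the slope *sign* is the scientific
   output, not its magnitude.

No raw clinical volumes are available, so the package pairs the analysis
pipeline with a synthetic 3D phantom generator that emulates the statistical
structure above with known ground truth. Every stage of the pipeline is
therefore testable end to end, and the phantom's defaults *are* the study
conditions.

## The phantom

`phantom_config()` + `generate_vessel_tree()` + `render_volume()` produce one
side of one case:

* **Diameter distribution.** Defined directly by its quantile function — a
  monotone piecewise-linear interpolant through the anchors
  (0, 0.08), (0.25, 0.29), (0.5, 0.37), (0.75, 0.50), (1, 1.3) mm. No
  two-parameter family can satisfy all three quartiles simultaneously
  (Q3/median ≠ median/Q1), so the quartiles are honoured by construction.
  `sample_diameters()` draws by randomized **stratified** inverse-transform
  sampling: one uniform per probability stratum, shuffled. Each draw is
  marginally exact, and sample quartiles converge at O(1/n) instead of
  O(1/√n) — a 2008-point sample reproduces the anchors to well under
  0.01 mm, which independent draws cannot guarantee (the upper anchor
  segment has slope 1.3−0.5 mm over 0.25 probability, putting the standard
  error of an iid Q3 near 0.015 mm).
* **Geometry.** Vessels are curvature-bounded random walks, roughly parallel
  to the skin, seeded uniformly en face and exponentially in depth (mean
  6 mm), with single-generation bifurcations. The depth component
  mean-reverts to the seeding depth, so the latent per-layer vessel length
  follows the seeding profile — that, plus optical attenuation, makes the
  density profile decrease with depth. Many short vessels (8–20 mm) rather
  than few long ones keep the spatial coverage well mixed, which is what
  bounds the case-to-case variance of ROI-pooled density (~1 pp).
* **Coverage calibration.** Growth stops when the binarised en-face
  footprint of the 0–2.5 mm layer reaches the side's target (28.2%
  reconstructed, 19.8% contralateral — the cohort means). The footprint is
  predicted by *voxelising the tube geometry with the same rasteriser the
  renderer uses*, not by an analytic length × diameter product: at sub-voxel
  diameters rasterisation quantisation breaks the analytic estimate, while
  the closed loop makes generation and measurement agree by construction at
  any voxel pitch.
* **Rendering.** Tubes are rasterised at their local diameter (sub-voxel
  vessels are guaranteed a single-voxel trace); vessel intensity is
  `240 · exp(−μ_eff z)` with μ_eff = 0.15 /mm — the simplest monotone
  surrogate for optical attenuation, as no optical model is specified for
  the device. The tissue background is a baseline of 28 with additive
  Gaussian noise (sd 12), clipped to 0–255; air above a displaced surface is
  0. A zero-mean background would leave nothing for surface detection to
  detect, hence the baseline; the noise scale keeps the false-foreground
  rate at threshold 75 below 10⁻⁴ per voxel. With these constants the
  attenuated vessel signal crosses the binarisation threshold near 11 mm
  depth, reproducing the loss of deep signal.
* **Remodeling.** Reconstructed-side anchors are scaled by
  `exp(−rate · interval)` with a floor at 0.08 mm. The default rate,
  0.01/month, puts the small-vessel proportion near 55–60% at 26–30 months —
  the range the per-case proportions motivate — and is not adjusted
  thereafter.
* **Contact defects.** Optionally, the skin surface is displaced into the
  volume by a gap depth over a stated areal fraction (a strip along one
  edge), emulating insufficient probe–skin contact.

`render_mask()` samples the *binarised* image directly from the same model
(thresholding Gaussian noise is a per-voxel Bernoulli event) and is used
where only the mask is needed; it is distributionally identical to
`binarize(to_grayscale(render_volume(...)))` at a fraction of the cost.

## The pipeline

* **Surface and QC** (`detect_surface()`, `assess_contact()`): per en-face
  column, the surface offset is the first depth whose 3 × 3-smoothed
  intensity exceeds the surface threshold (default 20); the offset map is
  3 × 3 median-filtered. A column is in contact when its offset is ≤ 0.5 mm;
  a side with contact fraction below 0.9 is excluded from density analysis.
  The quantitative criterion (0.5 mm, 0.9) is a repository decision — the
  study states the exclusions but not a numeric rule. Depth is referenced to
  the detected surface per column, exactly the correction that insufficient
  contact makes impossible.
* **ROIs** (`divide_quadrants()`, `select_rois()`, `extract_roi()`): the
  en-face plane is partitioned at the nipple centre; each quadrant's
  30 × 30 mm ROI has its inner corner on the quadrant diagonal at areola
  radius + 2 mm — a concrete formalisation of "just outside the areola
  border" that provably excludes the areola disc and the axis-aligned
  marking positions. The default phantom extent is 80 × 80 mm with a 12 mm
  areola: four 30 mm ROIs outside an areola disc geometrically require an
  en-face extent of at least `2 ((r + 2)/√2 + 30)` mm, which a 60 mm field
  cannot satisfy for any areola radius.
* **Density** (`to_grayscale()`, `binarize()`, `density_profile()`):
  binarisation is strictly `> 75` ("pixels above the threshold"); layers are
  half-open, so a corrected depth of exactly 2.5 mm belongs to layer 2. The
  four ROIs are pooled into a single ratio per layer (the literal reading of
  the density formula), not averaged per ROI. The default counting
  convention is **per-layer 2D projection**: a pixel counts as vessel in a
  layer if any voxel of its column within that layer is foreground — i.e.
  the binarised layer image a viewer displays. A 3D voxel-counting
  convention (`method = "voxel"`) is provided as well; both are tested
  against brute-force oracles exactly. Projection is the default because
  "pixels in each layer" describes 2D layer images, and because a ~28% *3D
  lumen fraction* in a 2.5 mm slab is not physiologically meaningful tissue,
  whereas a 28% projected coverage is.
* **Caliber** (`measure_diameters()`, `derive_cutoffs()`,
  `classify_diameter()`, `caliber_proportions()`): the manual protocol —
  measure where vessels are clearly visible and relatively straight, avoid
  widened bifurcation zones — is replaced by a deterministic surrogate:
  3D homotopic thinning to one-voxel centrelines, branch-point detection
  (≥3 skeleton neighbours), exclusion of skeleton voxels within 2 × local
  diameter of any branch point, straightness filtering (11-voxel windows
  with ≤1 voxel chord deviation), one measurement per straight run at the
  window of minimal deviation, and diameter = 2 × EDT × spacing. Every
  heuristic constant is an exposed parameter. Measurements are taken on the
  3D mask (not a projection) to avoid projection-induced overlap widening,
  and are restricted to the optically resolvable depth (`visible_depth()`,
  ≈12.8 mm at the defaults) — deeper voxels fall below the binarisation
  threshold and contribute only noise-gated fragments.
* **Quartiles** are linear interpolation between order statistics at
  positions (n−1)p + 1 (`quantile(type = 7)`, the convention of the
  numerical environment the analysis emulates); cutoffs are the first/third
  quartiles rounded half-up to 0.1 mm (0.29 → 0.3, 0.50 → 0.5). Rounding is
  implemented as `floor(10x + 0.5 + ε)/10` with ε = 10⁻⁹ to keep half-up
  semantics under binary floating point.
* **Comparison** (`side_difference()`, `fit_trend()`, `summarize_values()`,
  `build_report()`, `run_study()`): OLS via `lm()`; the medium-class trend
  is computed and reported even where no trend is expected — absence of a
  trend is a reportable outcome. Summaries are descriptive only (median and
  range, or mean ± sd with the n−1 denominator); no inferential statistics,
  matching the study's explicitly descriptive design. `run_study()` isolates
  per-case failures (partial studies are valid outputs, mirroring the
  different case subsets per endpoint) and writes a manifest from which
  every output is regenerable.

## Numerical and reproducibility choices

* Coordinates are 0-based and intervals half-open throughout; voxel *i*
  spans `[i·s, (i+1)·s)` mm with centre `(i + 0.5)·s`.
* All randomness flows from one master seed; per-case seeds are
  `seed · 1000 + case`, and each generation/render stage re-seeds with a
  fixed offset, so reruns are bit-identical and stages are insensitive to
  one another's RNG consumption.
* The EDT used by the measurement operator is the exact Euclidean transform,
  computed shell-capped at the maximum measurable radius (distances beyond
  the caliber range are never consulted); it is tested for exact agreement
  with the full separable transform.
* Degenerate inputs error loudly: missing voxel spacing, empty depth layers,
  all-equal diameter samples, collapsing rounded cutoffs, all-identical
  intervals in a trend fit.

## Voxel pitch and problem sizes

The phantom's default pitch is 0.125 mm, which resolves the smallest
modelled vessel (0.08 mm renders as a single-voxel trace, flagged here
explicitly). The analyses choose their pitch per endpoint:

* **Density** runs at 0.25 mm (five case pairs; the closed-loop calibration
  is pitch-invariant, and layer densities are pitch-robust).
* **Caliber and trends** run at 0.125 mm. This is not negotiable downward:
  the diameter estimate is quantised to multiples of two voxel spacings, so
  at 0.25 mm every vessel thinner than ~0.55 mm measures exactly 0.5 mm, the
  derived lower cutoff collapses onto the measurement floor, the small class
  empties, and the remodeling signal vanishes. At 0.125 mm the sub-voxel
  placement of vessel axes spreads the quantisation and the shift is
  recovered.

The test suite uses two-case studies and five-pair density runs at these
pitches; the trend check runs ten eight-case studies at 0.125 mm.

## What the phantom does and does not show

The generator emulates the *statistical* structure: paired sides, calibrated
superficial coverage, the anchored caliber distribution, attenuation,
interval-dependent remodeling, and contact defects. It does not model
photoacoustic wave physics, transducer geometry, reconstruction artifacts,
anatomically realistic vascular topology (no arterial/venous hierarchy, no
anatomical atlas), oxygenation contrast, or operator variability in manual
measurement. Passing tests therefore demonstrate that the *pipeline*
recovers known ground truth under the study's statistical conditions — not
that the pipeline would behave identically on device data. The measurement
operator also carries a known positive bias of roughly half a voxel spacing
per radius (distance to the nearest background voxel centre overshoots the
tube surface); cutoffs derived from measured contralateral data absorb this
bias exactly as the original protocol's cutoffs absorb operator bias.
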