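# pavasc — depth-resolved vascular morphometry for photoacoustic breast imaging

After breast reconstruction with autologous fat grafting (AFG), graft
survival depends on revascularisation from the recipient bed. Photoacoustic
imaging (PAI) maps hemoglobin-rich structures in 3D without contrast agents,
so vascular changes in the reconstructed breast can be quantified against
the non-operated breast as a within-patient control. `pavasc` implements
that quantification as a tested, reusable pipeline, for imaging scientists
and plastic-surgery researchers working with volumetric PAI data — plus a
synthetic vascular phantom so every stage runs and is verified without any
clinical data.

## What it computes

**Depth-stratified vascular density.** Within four periareolar 3 × 3 cm
ROIs (one per breast quadrant, placed just outside the areola), volumes are
converted to 8-bit grayscale, binarised at a fixed threshold of 75, and the
vascular density of each 2.5 mm depth layer is

    density(layer) = 100 · (foreground pixels in layer) / (total pixels in layer),

with eight half-open layers [0, 2.5), …, [17.5, 20) mm measured from the
*detected* skin surface per image column. Sides with probe–skin contact
over less than 90% of the field are excluded (the depth reference is
unreliable there).

**Vessel calibers.** Diameters are measured automatically on the binarised
mask: 3D skeletonisation, branch-point exclusion (2 × local diameter),
straight-window selection, and diameter = 2 × (Euclidean distance
transform) × voxel spacing. Pooled contralateral diameters define the
classification cutoffs: quartiles by linear interpolation of order
statistics — Q1 0.29, median 0.37, Q3 0.50 mm for the anchored default
distribution — rounded to 0.3 and 0.5 mm. Classes are small (< 0.3 mm),
medium (0.3–0.5 mm, boundaries inclusive), large (> 0.5 mm).

**Remodeling trends.** For each caliber class, the side difference of
proportions (reconstructed − contralateral) is regressed on the
postoperative interval (months) by ordinary least squares; the slope signs
are the finding (small ↑, large ↓ with longer intervals).

**Synthetic phantom.** Paired volumes with known ground-truth vessel trees:
diameters drawn through a quantile-anchored distribution, growth calibrated
in closed loop so the superficial binarised coverage hits 28.2%
(reconstructed) / 19.8% (contralateral), single-exponential depth
attenuation (μ_eff = 0.15 /mm), Gaussian background noise, remodeling as an
interval-dependent shrinkage of the diameter anchors, and optional
probe-contact defects.

## Worked example

```r
library(pavasc)

# one simulated case pair at 0.25 mm analysis pitch
cfg_r <- phantom_config("reconstructed", spacing_mm = 0.25)
cfg_c <- phantom_config("contralateral", spacing_mm = 0.25)
bundle <- make_case(cfg_r, cfg_c, interval_months = 12, seed = 101)

prof <- side_profiles(bundle)   # surface -> QC -> ROIs -> binarise -> layers
round(prof$reconstructed$density_pct, 1)
#> [1] 28.8 25.9 17.5  8.7  4.8  0.7  0.1  0.1
round(prof$contralateral$density_pct, 1)
#> [1] 20.4 14.4  9.1  5.7  3.4  0.4  0.0  0.1

# caliber cutoffs from a pooled synthetic contralateral sample
cs <- derive_cutoffs(sample_diameters(2008, seed = 1))
cs
#> <cutoff_set> quartiles 0.290 / 0.370 / 0.500 mm (n = 2008) -> cutoffs 0.3 / 0.5 mm
```

The reconstructed side is denser in the superficial layer (28.8% vs 20.4%
here), both profiles fall with depth as the excitation light attenuates, and
the pooled sample reproduces the quartile-derived cutoffs. The numbered
scripts under `analysis/` run the full study — phantom cohort, density
profiles, caliber cutoffs, interval trends, cohort summaries — writing
tables and figures under `results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_density_profiles.R
Rscript analysis/03_caliber_cutoffs.R
Rscript analysis/04_trend_analysis.R
Rscript analysis/05_cohort_summaries.R
```

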