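# mammoseg

Fully automatic segmentation of masses in mammographic regions of
interest (ROIs), for researchers building computer-aided detection
pipelines and for anyone who needs a deterministic, testable
implementation of the classic two-stage recipe:

1. **Noise reduction** — Perona–Malik anisotropic diffusion by default
   (average and Gaussian filters are available for comparison), because
   watershed flooding is extremely noise-sensitive;
2. **Coarse segmentation** — a marker-controlled watershed: foreground
   and background markers are derived automatically (morphological
   reconstruction, regional maxima, Otsu background), and the Sobel
   gradient surface is flooded from them by a deterministic priority
   queue; the brightest catchment basin is the candidate mass;
3. **Refinement** — a Chan–Vese region-based level set initialized from
   the watershed mask. The contour is the zero level of a signed field
   φ (negative inside) evolved to minimize the two-phase energy

   E(C, c₁, c₂) = λ₁ ∫_inside (I − c₁)² + λ₂ ∫_outside (I − c₂)² + μ·|C|,
   λ₁, λ₂ ≥ 0, μ ≥ 0,

   where c₁, c₂ are the region mean intensities and |C| is the contour
   length.

No seed point, contour or prompt is ever requested: the pipeline runs
unattended on every input.

Segmentations are scored against a reference mask with the six
overlap ratios built from pixel counts TP, FP, FN:
Hitting = TP/(TP+FN), Missing = FN/(TP+FN), OverHitting = FP/(TP+FN),
RelativeHitting = TP/(TP+FP), RelativeMissing = FN/(TP+FP), and
Kappa = 2·Hitting/(2·Hitting+Missing+OverHitting), which is
algebraically the Dice coefficient 2TP/(2TP+FP+FN).

Because clinical mammograms cannot ship with a package, a deterministic
phantom generator produces bright, soft-edged masses on textured noisy
backgrounds with exact ground-truth masks; the whole test suite runs on
phantoms.

## Worked example

```r
library(mammoseg)

ph  <- generate_phantom(phantom_spec(seed = 3))   # image + ground truth
fit <- segment_mass(ph$image, reference = ph$mask)
fit
#> Mass segmentation (watershed + level set)
#>   image: 256 x 256 px
#>   watershed regions: 8; coarse mass area: 4737 px
#>   level set: 16 iterations (converged); final mass area: 4926 px
#>   vs reference: Hitting 0.94, Missing 0.06, OverHitting 0.04,
#>                 RelativeHitting 0.96, RelativeMissing 0.06, Kappa 0.95
```

The print shows the two stages: the watershed found 8 catchment
regions and selected a 4737-pixel coarse mass; the level set expanded
and smoothed it to 4926 pixels. Against the known disk, 94% of the
true mass area is recovered (Hitting), false area is 4% of the mass
size (OverHitting), and the Dice-equivalent Kappa is 0.95.
`plot(fit)` displays the ROI with both masks; `summary(fit)` adds
stage timings and raw pixel counts.

Evaluating any external mask pair is one call:

```r
compute_metrics(list(tp = 4517, fp = 635, fn = 825))
metrics_report(list(tp = 4517, fp = 635, fn = 825))  # 2-decimal view
#>  hitting  missing  over_hitting  relative_hitting  relative_missing  kappa
#>     0.85     0.15          0.12              0.88              0.16   0.86
```

A command-line front end (`inst/cli/mammoseg.R`) wraps the same
functions: `segment`, `evaluate`, `phantom`, `compare-filters`, with
masks written as 0/255 PNG, metrics as CSV/JSON and provenance as
YAML.

## Package tour

| Area | Functions |
| --- | --- |
| Raster I/O & grids | `read_image`, `write_image`, `read_mask`, `write_mask`, `quantize_to_256`, `downsample`, `downsample_mask` |
| Denoising | `mean_filter`, `gaussian_filter`, `anisotropic_diffusion`, `denoise` |
| Watershed stage | `gradient_magnitude`, `regional_maxima`, `extract_markers`, `marker_watershed`, `select_mass_region`, `watershed_region_count` |
| Level set | `init_from_mask`, `region_means`, `chan_vese_energy`, `chan_vese` |
| Evaluation | `confusion`, `compute_metrics`, `metrics_report`, `dice` |
| Phantoms | `phantom_spec`, `generate_phantom`, `standard_phantom_suite` |
| Pipeline | `pipeline_config`, `read_config`, `segment_mass`, `compare_filters` |

The methods vignette (`vignettes/methods.Rmd`) documents the model,
every tunable parameter, the numerical choices and the known
limitations.
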