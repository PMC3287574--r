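---
title: "Methods: two-stage mass segmentation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage mass segmentation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoseg)
```

## The problem and the model

Masses in mammograms have ill-defined boundaries and overlap
fibro-glandular tissue, which defeats simple thresholding and makes
manual delineation slow and observer-dependent. `mammoseg` implements
a fully automatic two-stage segmentation of a region of interest (ROI)
cropped around a suspected mass.

**Stage 1 — marker-controlled watershed.** The Sobel gradient
magnitude of the (denoised) ROI is treated as topography. A plain
watershed floods every regional minimum and fragments the image into
thousands of catchment basins on a noisy mammogram; marker control
fixes this by flooding only from designated seeds. Markers are
computed with no user interaction:

* the denoised image is simplified by opening-by-reconstruction
  followed by closing-by-reconstruction with a disc (radius
  `markers.disk_radius`, default 10 px), which levels texture smaller
  than the disc while preserving the shape of larger structures;
* foreground markers are the 8-connected regional maxima of the
  simplified image, eroded by a disc of radius
  `markers.erosion_radius` (default 2 px) and filtered to components
  of at least `markers.min_area` pixels (default 20);
* the background marker is every pixel below the global Otsu
  threshold at city-block distance at least `markers.bg_distance`
  (default 15 px) from all foreground components.

Flooding is a priority queue ordered by (gradient height, insertion
sequence). The FIFO tie-break makes the labelling deterministic:
reruns are bit-identical, and an independent brute-force flood
simulation reproduces it exactly (this equivalence is a test). Every
pixel receives a marker label — no one-pixel dam lines are kept,
because the next stage only needs a region mask. Among the foreground
catchments, the one with the highest mean original intensity (ties:
larger area, then smaller label) is the coarse mass mask.

**Stage 2 — Chan–Vese refinement.** The coarse mask initializes a
region-based active contour. The contour is the zero level of a signed
field $\varphi$ (negative inside), and the segmentation minimizes the
two-phase piecewise-constant energy

$$E(C, c_1, c_2) = \lambda_1\!\!\int_{\text{inside}(C)}\!\!(I-c_1)^2
 + \lambda_2\!\!\int_{\text{outside}(C)}\!\!(I-c_2)^2 + \mu\,|C|,
 \qquad \lambda_1,\lambda_2 \ge 0,\ \mu \ge 0,$$

with $c_1, c_2$ the inside/outside mean intensities and $|C|$ the
contour length. Intensity is normalized to $[0,1]$ inside this module
so the weights are scale-free. Because the model is region-based it
tolerates the weak, partial edges typical of masses, and the length
penalty yields the smooth closed boundary that shape analysis needs.
The watershed initialization removes the level set's two classical
drawbacks: the need for a manual initial contour, and slow convergence
from a distant initialization.

### Evolution details

Each iteration recomputes $c_1, c_2$ as the means over the current
sharp partition $\{\varphi<0\}$, $\{\varphi\ge 0\}$ — these are the
exact minimizing constants of the discretized energy — then takes the
explicit step

$$\varphi \mathrel{+}= \mathrm{d}t\,\delta_\varepsilon(\varphi)\,
 \bigl[\mu\,\kappa(\varphi) + \lambda_1 (I-c_1)^2
 - \lambda_2 (I-c_2)^2\bigr],$$

whose signs follow the negative-inside convention: a pixel resembling
$c_1$ is pushed negative. $\kappa$ is the central-difference curvature
with a small denominator guard; the regularized Heaviside is the
smooth global variant
$H_\varepsilon(z)=\tfrac12(1+\tfrac2\pi\arctan(z/\varepsilon))$ with
$\delta_\varepsilon = H_\varepsilon'$, whose everywhere-positive
support lets the contour create or remove interior regions without
reinitialization.

Numerical choices that matter:

* **Interface-centred signed distance.** `init_from_mask()` places the
  zero level on the inter-pixel interface (a pixel adjacent to the
  boundary has $|\varphi|=0.5$). With this centring the lattice sum of
  $\delta_\varepsilon(\varphi)\,|\nabla\varphi|$ integrates to one
  across the contour, so the co-area estimate of $|C|$ is unbiased —
  for a disk of radius 30 px it reproduces $2\pi r$ within about 1%
  (a test asserts 10%).
* **Working band.** $\varphi$ is clamped to $\pm 3$ px after each
  step. $\delta_\varepsilon$ decays like $\varphi^{-2}$, so an
  unclamped far field effectively never moves; the band plays the role
  of reinitialization while leaving the contour neighbourhood
  untouched. (An optional `reinit_every` switch re-snaps the full
  signed distance; it is off by default.) The banded field is also why
  the update uses sharp rather than Heaviside-weighted means: at
  $|\varphi|=3$ the arctan tail still carries weight 0.10, so tens of
  thousands of background pixels would contaminate the inside mean and
  cancel the data force.
* **Step size and backtracking.** On the normalized intensity scale
  the driving force near the contour is of order $10^{-3}$
  (forces $10^{-2}$–$10^{-1}$ times $\delta_\varepsilon \le 1/\pi$),
  so the default step `dt = 100` moves the contour roughly one pixel
  per iteration. Stability comes from energy backtracking: a step that
  would raise the energy by more than $10^{-6}$ (relative) is retried
  with a halved step, and if fifteen halvings find no descent the
  evolution is at a discrete minimum and stops. This makes the
  recorded energy history non-increasing by construction — an
  asserted invariant, not an aspiration.
* **Convergence.** Evolution also stops when the mean fraction of
  pixels changing sign over a 5-iteration window falls below
  `tol = 1e-4` (about 6 pixels per iteration on a 256×256 ROI), or at
  `max_iter = 200`.
* **Degenerate inputs.** A constant image leaves the model
  unidentifiable ($c_1=c_2$); the fit is flagged degenerate
  immediately and the initial state is returned. If a region empties
  during evolution the last valid state is returned with the same
  flag, and the pipeline falls back to the coarse mask with a warning.

### Parameter summary

| Parameter | Default | Units | Meaning |
| --- | --- | --- | --- |
| `denoise.iterations` | 15 | steps | diffusion time; more steps, smoother |
| `denoise.kappa` | 30 | intensity (0–255) | edge-stopping scale: gradients well above it are preserved |
| `denoise.rate` | 0.25 | – | explicit-step constant; must stay in (0, 0.25] for stability |
| `denoise.conduction` | exponential | – | $g(s)=e^{-(s/\kappa)^2}$; `rational` favours wide regions |
| `markers.disk_radius` | 10 | px | reconstruction disc; texture smaller than this is levelled |
| `markers.erosion_radius` | 2 | px | marker shrinking, detaches weakly joined maxima |
| `markers.min_area` | 20 | px | minimum surviving foreground component |
| `markers.bg_distance` | 15 | px | clearance between background marker and foreground |
| `levelset.lambda1/2` | 1 | – | data-term weights on the normalized scale |
| `levelset.mu` | 0.1 | – | length penalty; larger values smooth more and can amputate lobules |
| `levelset.epsilon` | 1 | px | Heaviside width in $\varphi$ units |
| `levelset.dt` | 100 | – | step size (see above; backtracking guards it) |
| `levelset.tol` | 1e-4 | fraction | sign-change convergence threshold |
| `io.downsample_factor` | 1 | – | block-mean reduction before processing |

The standalone `downsample()` defaults to factor 4 — a typical
reduction when film-digitized mammograms are brought down to desk
scale and 256 gray levels — but the pipeline default is 1 because the
phantom ROIs are already small. When downsampling is active the
reference mask is reduced by majority vote and metrics are computed at
processing resolution. The package-wide rounding convention is half
away from zero, used for 8-bit quantization and the 2-decimal metric
report. The final mask is hole-filled and reduced to its largest
component (both switchable, both logged in the result object).

## Evaluation metrics

With pixel counts TP (reference ∩ segmentation), FP (segmentation
only) and FN (reference only):

$$\mathrm{Hitting}=\frac{TP}{TP+FN},\quad
 \mathrm{Missing}=\frac{FN}{TP+FN},\quad
 \mathrm{OverHitting}=\frac{FP}{TP+FN},$$
$$\mathrm{RelativeHitting}=\frac{TP}{TP+FP},\quad
 \mathrm{RelativeMissing}=\frac{FN}{TP+FP},$$
$$\mathrm{Kappa}=\frac{2\,\mathrm{Hitting}}
 {2\,\mathrm{Hitting}+\mathrm{Missing}+\mathrm{OverHitting}}
 = \frac{2\,TP}{2\,TP+FP+FN}.$$

Kappa is computed from the unrounded ratios (rounding first changes
nothing on the published cases but is lossier in general) and is
algebraically the Dice coefficient. True negatives are never counted:
in an ROI the background would dominate them. Note the identities
that do and do not hold: Hitting + Missing = 1 always, and swapping
reference and segmentation exchanges Hitting with RelativeHitting and
OverHitting with RelativeMissing while leaving Kappa unchanged; but
RelativeHitting + RelativeMissing = (TP+FN)/(TP+FP) is not 1 in
general, and OverHitting and RelativeMissing are unbounded above.

## The phantom generator

Clinical DDSM-style images cannot be redistributed with a package, so
all tests run on synthetic phantoms with exact ground truth:

$$I = \mathrm{clip}_{[0,255]}\bigl(\text{background} + \text{texture}
 + \text{contrast}\cdot\sigma\!\bigl(\tfrac{r - d}{\text{softness}}\bigr)
 + \text{noise}\bigr),$$

a sigmoid-edged disc (the soft edge models ill-defined mass
boundaries) over a low-frequency texture field — seeded white noise
smoothed by a wide Gaussian (sd 16 px, circular convolution so the
field is stationary to the borders) and rescaled to a chosen
amplitude — plus per-pixel Gaussian noise. The ground-truth mask is
the exact disc $d \le r$, independent of noise. Generation is
bit-reproducible per seed and leaves the session RNG untouched.

The standard suite is twenty 256×256 phantoms (seeds 0–19): radius
40 px, contrast 80, softness 6 px, background 100, texture amplitude
10, noise sd 15. These values give a clearly visible but noisy mass
(contrast ≈ 5 noise sd) over clutter strong enough to provoke
thousands of spurious watershed basins when undenoised — the regime
the pipeline is designed for. On this suite the pipeline's mean final
Dice is about 0.91 and level-set refinement does not degrade the
watershed mask on at least 90% of fixtures; the four denoising options
order the uncontrolled watershed basin count as anisotropic ≤ Gaussian
≤ mean ≤ none (`compare_filters()` reproduces the table).

What the phantoms do **not** model: spiculated margins, compression
and scatter physics, pectoral muscle and skin-line structures,
multi-mass ROIs, and calcifications. Passing on phantoms therefore
demonstrates the algorithmic properties (determinism, convergence,
refinement, noise robustness) rather than clinical accuracy.

## Design choices on open points

* **Marker recipe.** "Marker-controlled" underdetermines how markers
  are found; the reconstruction/regional-maxima/Otsu recipe above is
  classical, deterministic and interaction-free, and is isolated
  behind `extract_markers()` so it can be swapped.
* **Over-segmentation measure.** The filter comparison counts the
  catchment basins of the *plain* gradient watershed
  (`watershed_region_count()`), i.e. the fragmentation that marker
  control exists to suppress. Counting marker-controlled regions
  instead would measure the marker recipe (whose reconstruction step
  itself suppresses pixel noise) rather than the filters.
* **Mass selection.** Highest mean original intensity with
  area/label tie-breaks; on a single-mass ROI brightness is the most
  reliable discriminator and the rule is deterministic.
* **Resampling.** Block means rather than decimation, to avoid
  aliasing in the gradient; masks by majority vote.

## Known limitations

* If texture splits the mass into several regional-maxima components,
  the selection rule can pick a bright fragment; the level set then
  sometimes converges to a local minimum near that fragment instead of
  regrowing the full mass (one of the twenty standard fixtures does
  this, which is visible in the suite's mean Dice). Lowering
  `levelset.mu` or raising `markers.disk_radius` helps on such cases.
* The energy landscape is nonconvex; the backtracking guarantees
  monotone descent, not a global minimum.
* Single-mass ROIs only: no detection step, no multi-mass handling,
  no benign/malignant classification.
* Problem sizes in the test suite are chosen for a desk machine:
  256×256 phantoms, 64×64 exactness fixtures, ≤8×8 oracle grids
  (200 of them), 50 random diffusion fixtures.
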