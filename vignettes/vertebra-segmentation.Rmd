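---
title: "Vertebra detection and segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebra detection and segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertascan)
```

`vertascan` segments the cervical vertebral bodies C3–C7 in low-contrast
radiographs with a chain of classical, individually auditable stages. This
vignette is the package's own account of the science: the model behind each
stage, the parameters that matter and their defaults, the numerical choices
made where the design was genuinely open, what the synthetic test data does
and does not emulate, and the known limitations.

## Why local models

The spine's curvature varies strongly across flexion, neutral and extension
positions, so a single global statistical model of all five vertebrae
explains curvature variance at the expense of per-vertebra boundary
accuracy. The package therefore uses one *local* Active Shape Model (ASM)
per vertebral body. The price of locality is initialization: a local model
must start close to its vertebra. The whole first half of the pipeline
exists to provide that initialization from just two user clicks (the upper
anterior corner of C3 and the lower anterior corner of C7).

## Stage models and parameters

### Contrast-limited adaptive histogram equalization

Plain histogram equalization has almost no effect on cervical radiographs,
whose dynamic range is dominated by soft tissue. CLAHE equalizes each of
`tiles_x × tiles_y` contextual regions separately and blends the regional
transforms bilinearly between region centers, which removes the visible
tile boundaries that per-region equalization would otherwise create. To
avoid amplifying noise in homogeneous areas, each regional histogram is
clipped before equalization: bins are capped at `clip_limit` times the
uniform bin height and the clipped mass is redistributed uniformly.

Open design points, resolved as follows:

* **Transform definition.** Each region's mapping is its clipped cumulative
  distribution scaled to the full output range — monotone by construction.
* **Redistribution residue.** Uniform redistribution can push bins back
  over the cap. The residue is swept in a single second pass (cap again,
  spread the remainder once more). Pixel counts are conserved exactly, and
  the final bins can exceed the cap only by the small second-pass share.
* **Border band.** Outside the rectangle spanned by region centers the
  blending weights are clamped, which degenerates to linear interpolation
  along image edges and the nearest single transform at image corners.
* **Defaults.** `tiles 8×8`, `clip_limit 2.0`, `n_bins 256` — the
  conventional CLAHE operating point; the clip limit trades noise
  amplification (higher) against contrast gain (lower). Setting
  `clip_limit = n_bins` disables clipping and recovers plain regional
  equalization.

### Canny edge detection

Smoothing with a sampled Gaussian kernel (σ in pixels, kernel radius
`ceiling(3σ)`, symmetric border padding) is followed by the two 3×3 Sobel
masks, magnitude `sqrt(Gx² + Gy²)` and direction `atan2(Gy, Gx)` — the
two-argument arctangent keeps a vanishing `Gx` well defined. Non-maxima
suppression quantizes the direction into the four 45° sectors and keeps a
pixel only if its magnitude is at least that of both neighbours along the
gradient; hysteresis then applies the three-way rule (reject below `low`,
accept above `high`, accept in between only if connected to an accepted
pixel). Connectivity defaults to 8-neighbour; components are resolved on
the pixel adjacency graph. Thresholds can be absolute or quantiles of the
positive suppressed-magnitude distribution. A fourth-order recursive
smoothing backend (`smoother = "deriche"`) is provided whose per-pixel cost
is independent of σ; it agrees with direct convolution to well under 1%
RMS, so the two backends are interchangeable in effect.

The 1-pixel image border is zeroed after the Sobel stage: the masks do not
fit there, and extrapolated border responses would only seed spurious
contours.

### Corner detection by polygonal approximation

Edges are turned into ordered point chains by boundary following (chains
start at endpoints when one exists, 4-adjacent moves are preferred over
diagonal ones, and junctions break chains), then simplified with the
recursive Douglas–Peucker rule: if the farthest interior point from the
chord joining the extremities is within ε it is removed along with all
interior points, otherwise it is kept and the rule recurses on both halves.
Distances are measured to the chord *segment* (clamped projection), which
also bounds the error of removed points by ε even when the perpendicular
foot falls outside the chord. Ties for the farthest point break to the
lowest index, making the approximation deterministic. Closed rings are
split at their two mutually farthest points and each half is approximated
as an open polyline.

A vertex is a corner if its turning angle lies in 30°–150°: the lower bound
discards near-collinear vertices that merely track contour curvature, the
upper bound discards single-pixel reversal spikes from noise. The default
ε = 4 px is the only free parameter of this stage once the Canny parameters
are fixed, and the two are independent of each other.

### Localization from two clicks

A spine-curvature model — the mean of Procrustes-aligned anterior-corner
sequences, 10 landmarks (upper+lower anterior corner per vertebra, ordered
top to bottom) — is mapped onto the image by the *unique
orientation-preserving* two-point similarity transform taking its first
landmark to the C3 click and its last to the C7 click; reflections are
excluded since radiograph orientation is a fixed acquisition convention.
Each positioned landmark then takes the nearest detected corner within a
search radius (default a quarter of the inter-click distance divided by the
landmark count, ≈10 px at desk scale). Matching proceeds strictly top to
bottom, and candidates are restricted to corners whose projection onto the
click axis lies strictly below the previously matched one — this ordering
is what prevents the lower corner of one vertebra and the upper corner of
the next from swapping. A landmark with no candidate in range is flagged
and falls back to its model-predicted position, so a single missed corner
degrades rather than derails the initialization.

The package ships a synthetic-trained curvature model
(`default_curvature_model()`); users with annotated radiographs can train
their own with `build_curvature_model()`.

### Statistical shape machinery

Shapes are n×2 landmark matrices. Pairwise Procrustes alignment is the
closed-form complex least-squares solution; generalized alignment iterates
align-to-mean / re-mean until the mean stabilizes. The mean is normalized
to remove the similarity gauge (centred, unit centroid size, first-to-last
landmark axis held at a fixed reference angle) — without this the iteration
could drift in scale and rotation while all residuals stay unchanged. The
PCA model keeps the smallest number of eigenmodes of the landmark
covariance explaining 95% of variance by default. Mode coefficients are
clamped to ±3√λ, the standard ASM plausibility region. Projection of a
shape onto the model recovers the pose by Procrustes to the mean and the
coefficients by the orthonormal mode basis; the generate/project round trip
is the identity for in-range coefficients up to the (second-order) error of
linearizing pose removal.

### Active Shape Model search

The texture evidence at each landmark is its grey-level *gradient* profile:
the magnitude of the directional derivative of intensity, sampled at unit
steps along the landmark normal (perpendicular to the chord between the two
neighbouring landmarks, shape treated as closed), `2k+1` samples with
default `k = 6`, normalized by its sum of absolute values so the profile
carries edge *shape* rather than edge strength. Training collects these
profiles over images with known shapes and stores per-landmark mean and
covariance; the covariance is regularized with `δI`, `δ = 1e-6·trace/k`
(floored at 1e-8), so Mahalanobis matching stays well posed even on nearly
deterministic training sets.

Each search step evaluates `2·search_range + 1` candidate positions per
landmark (default range 4 px), picks the minimum-cost candidate (ties break
to the smallest displacement, making the optimum a fixed point), and
regularizes the proposed shape through the model (pose update plus clamped
coefficients). Iteration stops when the mean landmark movement drops below
`tol = 0.5` px, when the summed profile cost stops improving — the direct
operationalization of "the match is no more improved" — or at `max_iter =
50`. The profiles are matched on the *original* image, not the CLAHE
output: enhancement exists to make weak corners detectable, while profile
models should be trained and evaluated on the unaltered intensity field. No
multi-resolution pyramid is used; at the 4-px search range and with corner
anchoring the plain search already converges in a few iterations.

### Evaluation metrics

Segmentation error is the point-to-line distance: from each gold landmark,
the minimum distance to the natural cubic interpolating spline through the
fitted landmarks, parameterized by cumulative chord length. The minimum is
found by dense sampling (1000 points per landmark interval) plus local
golden-section refinement — equivalent to the perpendicular drop wherever
the foot of the perpendicular exists. Per-case errors are split into
success and failure distributions by iterative 3-standard-deviation
trimming (remove cases above mean+3·SD of the current success set,
recompute, repeat to a fixed point, seeded with the full sample; trimming
never reduces the success set below two cases). With 51-case batches the
failure rate is by construction a multiple of 1/51 ≈ 1.96%. Pixel lengths
convert to millimetres as `25.4/dpi`; at the 146 dpi of digitized film
archives this is ≈0.174 mm/px, commonly rounded to 0.2 mm.

## The synthetic test bed

`render_radiograph()` emulates the features of archival cervical
radiographs that drive algorithm behaviour: five brighter convex
quadrilateral bodies stacked along a curved axis (lateral bow 30 px at the
512-px desk scale), rounded corners (2 px radius — real vertebra corners
are not sharp, and this is precisely what stresses a geometric corner
detector), Gaussian-blurred boundaries ("blended contours", σ = 1.5 px),
poor contrast (body-over-background difference 60 of 255), a smooth
diagonal illumination ramp (amplitude 20) and additive Gaussian noise
(SD 4). These defaults were chosen once as a realistic low-contrast
operating point and define the package's study conditions; every rendered
scene carries exact ground truth (corners, dense boundaries, the
anterior-corner sequence and 12-landmark per-vertebra shapes), and
rendering is bit-reproducible per seed. Experiments use the 512-px desk
scale; the full archival scale (1763×1755) is available through
`image_size`.

What the generator does *not* emulate: soft-tissue and airway shadows,
overlapping structures (jaw, shoulders), speckle/Poisson noise statistics,
inter-vertebra fusion, osteophytes, and the full variability of clinical
vertebra shapes. Passing tests on this bed therefore demonstrate the
correctness and stability of the machinery — not clinical-grade accuracy.
The default shape, curvature and profile models are trained on the same
synthetic family (`default_vertebra_model()`, `default_curvature_model()`,
`default_profile_model()`) and are labelled synthetic; they are stand-ins
for models a user would train on annotated radiographs.

One deliberate generator choice concerns parameter-recovery experiments:
`sample_training_shapes()` standardizes the drawn mode coefficients to the
exact target standard deviation per mode (disable with
`standardize = FALSE`). A raw Gaussian draw of 200 shapes carries
`sqrt(2/200) ≈ 10%` sampling noise in each sample eigenvalue, which would
dominate any recovery measurement at that size; standardizing makes the
generator's variances exact ground truth of the generated set, so recovery
experiments measure the error of the Procrustes+PCA machinery itself
(empirically well under 1%).

## Numerical choices and degenerate inputs

* Intensities are doubles on the 0–255 scale (8-bit default; other depths
  via `max_level`). Coordinates are 1-based, `x` = column, `y` = row,
  origin top-left, matching R's matrix convention.
* Constant images: CLAHE maps them uniformly; Canny returns an empty edge
  map; profile sampling returns a zero profile (normalization guards the
  0/0 case).
* Degenerate shapes (all landmarks coincident, zero-length contours) raise
  errors rather than propagating NaNs.
* All tie-breaks (farthest point, minimum-cost candidate, equal-distance
  corners) are deterministic, and all stochastic fixtures are seeded, so
  identical inputs always give bit-identical outputs.
* Experiment sizes in the test suite (51-case batches, 200-shape recovery
  sets, 20-fixture improvement runs at the 512-px desk scale) were chosen
  as the package's standard small-scale study conditions.

## Known limitations

* The two ROI clicks are required; fully automatic ROI detection is out of
  scope.
* Merged or overlapping vertebrae can cause the corner matcher to confuse
  the lower corner of one body with the upper corner of the next; the
  ordering constraint prevents swaps but cannot disambiguate a shared
  corner. No mitigation is implemented.
* The point-to-line metric understates errors tangential to the contour.
* Default models are synthetic-trained; clinical use requires training on
  annotated radiographs of the target modality.
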