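# vertascan

Semi-automatic detection and segmentation of the cervical vertebral bodies
C3–C7 in spine radiographs, for vertebral mobility analysis. Cervical
radiographs have very poor contrast and blended bone contours, so neither a
global threshold nor a global spine model segments individual vertebrae
reliably; `vertascan` instead detects each vertebra locally and fits a local
statistical shape model to it. It is written for researchers working on
skeletal image analysis who need a fully testable pipeline: a seeded
synthetic radiograph generator with exact ground truth ships with the
package, so every stage can be exercised and measured without clinical
data.

## Method

Given a radiograph and two user-supplied points — the upper anterior corner
of C3 and the lower anterior corner of C7 — the pipeline runs:

1. **Enhance** — contrast-limited adaptive histogram equalization (CLAHE).
   The image is divided into contextual regions; each region's histogram is
   clipped at a contrast factor and equalized through its cumulative
   distribution, and every pixel is mapped through the four surrounding
   region transforms blended bilinearly,
   `s = (1−y)[(1−x)T_A(r) + xT_B(r)] + y[(1−x)T_C(r) + xT_D(r)]`.
2. **Edges** — Canny detection: Gaussian smoothing (direct convolution or a
   recursive approximation whose cost is independent of σ), Sobel gradients
   `G = sqrt(Gx² + Gy²)`, `θ = atan2(Gy, Gx)`, non-maxima suppression along
   the quantized gradient direction, and two-threshold hysteresis where
   mid-strength pixels survive only if connected to a strong pixel.
3. **Corners** — edge pixels are traced into ordered contours and
   simplified by Douglas–Peucker polygonal approximation (keep the farthest
   point from the end-to-end chord whenever its distance exceeds ε);
   approximation vertices with a substantial turning angle are corners.
   This is a geometric corner definition — the intersection of two segment
   lines — which is robust exactly where intensity-based detectors fail on
   low-contrast radiographs.
4. **Locate** — a statistical spine-curvature model (mean of
   Procrustes-aligned anterior-corner sequences) is anchored exactly on the
   two clicks by the unique two-point similarity transform; each landmark
   then takes its nearest detected corner, processed strictly top to bottom
   so upper/lower corners of successive vertebrae cannot swap.
5. **Segment** — per-vertebra Active Shape Model: a PCA shape model
   `x = x̄ + P b` (modes orthonormal, coefficients clamped to ±3√λ) is
   initialized on the matched anterior corners and refined by moving each
   landmark along its normal to the position whose grey-level gradient
   profile minimizes the Mahalanobis distance
   `(g − ḡ)ᵀ S⁻¹ (g − ḡ)` to the trained profile model, iterating until the
   landmarks stop moving.
6. **Evaluate** — point-to-line distance from each gold-standard landmark
   to the spline through the fitted landmarks, with a success/failure
   decomposition (a case is a failure if its error exceeds the success
   mean by 3 standard deviations) and px↔mm conversion (25.4/dpi).

## Worked example

```r
library(vertascan)

# a 512x512 synthetic cervical radiograph with exact ground truth
r <- render_radiograph(synthetic_spec(seed = 7))

# the two "user clicks" come from the ground truth here
res <- run_pipeline(r$image, r$truth$clicks)

sum(res$anchors$matched)                      # corners matched to landmarks
#> [1] 10
sapply(names(res$shapes), function(v)
  round(mean(point_to_line_distance(r$truth$shapes[[v]], res$shapes[[v]],
                                    closed = TRUE)), 2))
#>   C3   C4   C5   C6   C7
#> 0.36 0.30 0.54 0.40 0.34
```

All 10 anterior-corner landmarks were matched to detected corners, and the
final Active Shape Model contours lie within about half a pixel (≈0.1 mm at
146 dpi) of the true vertebra boundaries on this fixture.

A command-line interface wrapping the same functions is installed at
`inst/scripts/vertascan`:

```sh
Rscript inst/scripts/vertascan simulate --seed 9 --out sim
Rscript inst/scripts/vertascan run sim/radiograph.png \
    --roi 193.7,106.7,193.7,405.3 --out contours.json
Rscript inst/scripts/vertascan evaluate --gold sim/gold_shapes.csv \
    --fitted contours.json --out report.csv
```

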