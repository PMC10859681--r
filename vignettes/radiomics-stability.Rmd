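---
title: "Methods: quantifying radiomics feature stability under enhancement and segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radiomics feature stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

# The question the package answers

A radiomics feature is a scalar computed from an image and a region of
interest. Its clinical value depends on *test–retest stability*: if the same
lesion is delineated again — by the same observer months later, by a different
observer, or by a semi-automated algorithm — a useful feature should return
nearly the same value. `radstab` measures that stability with intraclass
correlation coefficients (ICC) from a two-way ANOVA and asks how it changes
across three segmentation arms: manual delineation, region-growing seeded
active contours, and the same active contours run on a CLAHE-enhanced image.

Because clinical DWI-MRI images cannot be redistributed, the package ships a
synthetic phantom module that generates the whole study design — a cohort of
subjects, repeated delineations, all noise sources — from a seed. Every claim
the test suite makes is therefore reproducible from code alone.

# The phantom model

A phantom slice is `image = bias × piecewise intensity + Rician noise`,
clipped to [0, 1]:

* The lesion is a rotated ellipse of constant intensity (default 0.85) on a
  darker background (default 0.25) — the bright-lesion-on-dark-background
  contrast of high-b-value DWI.
* Noise is Rician, `sqrt((s + g1)² + g2²)` with `g1, g2 ~ N(0, σ²)`, the
  standard model for magnitude MR images; at zero signal it reduces to
  Rayleigh, which the tests verify against the closed-form mean `σ√(π/2)`.
  Default σ = 0.05 in normalized intensity units — visually comparable to a
  moderate-SNR clinical slice.
* The bias field is `1 + a·p(x, y)` with `p` a seeded quadratic polynomial
  rescaled to [−½, ½]; default peak-to-peak amplitude `a = 0.2`. It is a
  smooth surrogate for receive-coil inhomogeneity, not a physical coil model.

**Observer model.** Repeat delineations are simulated by displacing the mask
boundary radially: displacements are drawn i.i.d. at 64 equally spaced angles,
smoothed with a periodic Gaussian kernel over angle (correlation length
`smoothness`, default 30°), and the kernel is renormalized to unit ℓ2 norm so
the marginal displacement SD stays at `boundary_jitter_sigma`. Re-rasterization
assumes the mask is star-shaped about its centroid — true for the phantom
ellipses. `σ = 0` returns the input mask object unchanged, which is what makes
the "perfect reproducibility ⇒ ICC = 1" pathway exact rather than approximate.
No published calibration of human delineation variability is built in; jitter
magnitudes are free parameters of the experiment design.

**What the phantom does *not* emulate:** partial-volume boundaries, anatomical
texture inside the lesion, ghosting/motion artifacts, multi-focal disease, or
3-D continuity between slices. Passing the synthetic suites therefore shows the
*pipeline* behaves as specified, not that any particular clinical dataset would
yield the same ICC ordering.

# CLAHE

CLAHE is implemented from first principles. The image is divided into an
`NT = (8, 8)` tile grid (configurable); each tile's 256-bin histogram is
clipped at `ceiling = CL × tile_pixels` and the excess redistributed uniformly
over all bins in one real-valued pass — mass is conserved to machine precision
and no bin ends above `ceiling + excess/n_bins`. Tile mappings are the clipped
cumulative distributions, blended bilinearly between neighbouring tile centers
(edge tiles clamped). Two deliberate conventions:

* A tile whose pixels occupy a single histogram bin maps intensity to itself.
  Combined with blending written as `v + Σ wᵢ(mᵢ(v) − v)`, constant images are
  *exact* fixed points.
* `CL` is a fraction of the tile pixel count. The interface exposes it on
  (0, 1], with 0.9 the conventional operating point for this analysis; under
  this normalization values near 1 disable clipping almost entirely, so
  CLAHE ≈ plain adaptive histogram equalization there, and
  `CL = 1, NT = (1,1)` degenerates exactly to global histogram equalization
  (tested against a brute-force oracle).

Note a consequence the stability experiments make visible: with `CL = 0.9`,
tile-local equalization amplifies background noise strongly. Segmentation on
such an image only works because the edge indicator smooths first, and the
region-growing seed stage runs on the smoothed *unenhanced* image (the seed
marking is an observer action on the acquired slice, and raw-pixel growing on
a noise-amplified image is unusable).

# Level-set segmentation

The semi-automated arms evolve the geodesic active-contour flow

```
du/dt = g(I)(c + κ)|∇u| + ∇g·∇u,   mask = {u < 0}
```

* `g(I) = 1/(1 + (λ|∇(G_σ * I)|)²)` with pre-smoothing `σ = 1.5` px. The gain
  `λ` is needed because intensities are normalized to [0, 1]: a unit-contrast
  edge smoothed at σ = 1.5 has peak gradient ≈ 0.27, so the plain `1/(1+h²)`
  indicator never drops below ≈ 0.93 and cannot arrest a balloon within the
  standardized 100 iterations. The default `λ = 20` maps a contrast-0.5 edge
  to g ≈ 0.1. The rule of thumb is λ ≈ 2 / (peak smoothed edge gradient):
  high-contrast (unit) edges are better served by λ ≈ 10, because a larger
  gain saturates g ≈ 0 in a plateau around the edge and strands the front at
  the plateau rim a few pixels out.
* Sign conventions: `u` is the signed distance (negative inside), κ =
  div(∇u/|∇u|) is positive for convex fronts, balloon `c > 0` grows the
  region, and pure curvature flow shrinks a disk at `dr/dt = −1/r` (verified
  to 5% on a 128² grid).
* Numerics: explicit time stepping with upwind (entropy) differencing for the
  balloon and edge-advection terms and central differences for curvature;
  `dt = 0.5/(|c| + 4)` (the stability bound) unless overridden; curvature
  regularized by `|∇u|² + ε²`, ε = 1e−8; `u` re-initialized to a signed
  distance every 20 iterations via a Euclidean distance transform. The
  re-initialization cadence is configurable because it quantizes sub-pixel
  front motion: flows slower than ~1 px per cadence stall, so the pure
  curvature-flow validation runs with re-initialization at 100 iterations and
  `dt = 0.05`.
* The edge-advection term `∇g·∇u` follows the full geodesic flow; a
  `edge_advection = FALSE` switch drops it for the reduced form
  `g(c+κ)|∇u|`. A front collapse returns the empty mask with a `collapsed`
  attribute and a warning rather than an error, so batch runs can decide.
* The classical parametric snake energy (elasticity α, rigidity β, edge weight
  γ) is provided as an *evaluator* (`contour_energy()`) for inspection; the
  evolution pathway is the level set, with β fixed at 0 and α, γ absorbed
  into (κ, g).

Region growing is the maximal 4-connected component within `tol` of the seed
intensity (default 0.15 of the normalized range), implemented as iterated
masked dilation.

# The feature registry

Exactly 36 named features in fixed order; every extraction must return all of
them finite, which is what lets measurement tables downstream be complete.

* **GLCM (21).** Intensities inside the mask are quantized to 8 equal-width
  levels over the masked min–max range (range-relative, so adding a constant
  to the image changes nothing — tested). Co-occurrences at distance 1 are
  accumulated symmetrically for the four standard angles and normalized; the
  21 Haralick-family statistics are computed per angle and averaged. Entropies
  use base 2 with 0·log 0 = 0. The registry's duplicated "homogeneity" is
  resolved as the two standard variants (inverse difference and inverse
  difference moment); sum variance is centered on sum average; degenerate
  denominators (zero marginal SD, max(HX, HY) = 0) return 0 by convention.
* **First order (6).** Mean, population variance, skewness, kurtosis (plain,
  not excess), energy = Σ intensity² on raw masked values, entropy from a
  64-bin histogram. Zero-variance regions return skewness = kurtosis =
  entropy = 0 so vectors stay NaN-free.
* **Shape (9).** Area (pixel count); axis lengths / orientation / eccentricity
  from the moment-matched ellipse with the 1/12 pixel-extent correction;
  equivalent diameter √(4·area/π); convex area by rasterizing the pixel-center
  convex hull; solidity; perimeter as the Moore boundary-trace arc length with
  √2 diagonal steps. Orientation is degrees in (−90, 90] from the row axis,
  a fixed convention that makes the 90°-rotation tests exact statements.

# ICC estimation and reporting

For each (arm, feature), values form a complete `n × k` table (subjects ×
rater/session replicates). The two-way decomposition gives MS_R (rows), MS_C
(columns), MS_E (interaction residual), MS_W (within-row). The single-measure
coefficients are built from moment variance components, each truncated at
zero:

```
var_subject = (MS_R − MS_E)/k      var_rater = (MS_C − MS_E)/n
ICC(A,1) = var_subject / (var_subject + var_rater + MS_E)
ICC(C,1) = var_subject / (var_subject + MS_E)
```

Untruncated these reduce to the familiar mean-square forms. The truncation is
the standard non-negativity constraint of moment estimation; it keeps
estimates in [0, 1] (the scale on which the ICC is interpreted here) and makes
`ICC(C,1) ≥ ICC(A,1)` hold on every table, with equality exactly when
MS_C ≤ MS_E. Two deliberate conventions: a table whose cells are all identical
is ICC = 1 with a degeneracy flag (it arises legitimately from deterministic
re-extraction), and exactly-identical replicate columns short-circuit the
column/residual sums to zero so that case is *exactly* 1, not 1 − ε.

A `strict = TRUE` mode evaluates an alternative printed form of both
estimators — `(k+1)` in place of `(k−1)` on the error weight for A,1 and
`(MS_R − MS_W)/(MS_R + (k−1)MS_R)` for C,1 — for auditability. The strict
consistency form returns 1/k, not 1, for identical columns, which is why the
standard estimator is the default.

Reproducibility bins use half-open intervals Poor [−∞, 0.4), Fair [0.4, 0.6),
Good [0.6, 0.75), Excellent [0.75, 1]; as printed, the interior cut points
appear in two adjacent labels, so the half-open convention is what makes
binning deterministic. Arms are compared with a two-sided Wilcoxon rank-sum
test on their per-feature ICC values: exact by full enumeration of the midrank
permutation distribution when the pooled size is ≤ 12 (the enumeration is
valid with ties, which is why identical samples give exactly p = 1), otherwise
a normal approximation with tie and continuity corrections.

On Table-2-style summaries the report bins *features* (the registry has 36);
mean ± SD summaries use the population SD, matching "0.990 ± 0.005"-style
descriptive reporting.

# The experiment driver

`run_pipeline(experiment_config(...))` executes phantom → (CLAHE) →
segmentation → features → stability per arm. All randomness flows from the
single global seed through per-replicate derived seeds
`hash(seed, arm, subject, observer, session)`, so results are independent of
execution order and byte-identical across re-runs (asserted in the tests).
Stage failures abort with the arm and subject id. With `output_dir` set the
run writes `features.csv`, `icc.csv`, `bin_counts.csv`, and a JSON manifest
holding the parameter snapshot, seed, and a hash of the measurement table.

I/O supports 8/16-bit grayscale PNG and single-slice NIfTI (honouring
`scl_slope`/`scl_inter`; values already in [0, 1] are left untouched so float
round trips are lossless). The installed PNG bindings read but do not write
16-bit files, so the package carries a minimal 16-bit PNG encoder. DICOM is
not supported.

# Validation problem sizes

The shipped suites use: 1000 random measurement tables (n ∈ [2, 20],
k ∈ [2, 4]) against a loop-based sums-of-squares oracle at 1e−10; 100 random
8×8 GLCMs against a scalar textbook oracle at 1e−9; 20 noiseless unit-contrast
phantoms (96², 100 iterations, Dice ≥ 0.95 each) and 20 Rician σ = 0.05,
contrast-0.5 phantoms (median Dice ≥ 0.85); and a 30-subject, 2-session cohort
for the jitter → ICC recovery, where jitter 0 must give ICC = 1 for all 36
features and ICC must decrease in jitter (Spearman ρ < 0) for ≥ 90% of them.
These sizes keep the full suite near one minute while leaving the Monte-Carlo
checks comfortably away from their thresholds.

# Known limitations

* 2-D only; no 3-D level sets, volumes, or 3-D shape features.
* The phantom's lesion is homogeneous; texture features on phantoms reflect
  noise and bias-field structure, not biological heterogeneity.
* No ICC confidence intervals and no multiple-testing correction — the report
  is descriptive, matching the analysis it implements.
* The CLAHE clip-limit normalization is one of several in circulation; results
  at a given CL are only comparable across implementations sharing the
  fraction-of-tile-pixels convention.
* Observer jitter is radial and star-shaped; masks with deep concavities would
  need a different perturbation model.
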