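# radstab

Radiomics features — texture, intensity, and shape statistics extracted from a
segmented region of a medical image — are only useful biomarkers if they are
*stable*: re-drawing the lesion boundary, or re-running the segmentation two
months later, should not change them much. `radstab` quantifies that stability
for 2-D grayscale MRI slices (the motivating setting is diffusion-weighted MRI,
where restricted-diffusion lesions appear bright on a darker background) and
asks how it changes when the image is contrast-enhanced before segmentation.

The package implements the full analysis as composable, tested pieces:

* **Phantoms** — a synthetic cohort generator producing DWI-like slices with an
  elliptical lesion, Rician magnitude noise, a smooth multiplicative bias
  field, and a seeded observer model that re-draws lesion boundaries with
  spatially correlated radial jitter. Every downstream stage is testable with
  no clinical data.
* **Enhancement** — contrast-limited adaptive histogram equalization (CLAHE)
  written from first principles: per-tile histograms, clip-limit redistribution
  with exact mass conservation, and bilinear blending of tile mappings.
* **Segmentation** — three arms: ingested manual masks; region growing from a
  seed pixel; and a geodesic active-contour level set
  `du/dt = g(I)(c + κ)|∇u| + ∇g·∇u` run for a standardized 100 iterations,
  optionally on the CLAHE-enhanced image.
* **Features** — a fixed 36-entry registry: 21 gray-level co-occurrence matrix
  (GLCM/Haralick) texture features averaged over the four standard offsets,
  6 first-order intensity statistics, and 9 shape descriptors.
* **Stability** — two-way ANOVA intraclass correlation coefficients for
  absolute agreement and consistency,

  ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E)),
  ICC(C,1) = (MS_R − MS_E) / (MS_R + (k−1)MS_E),

  with variance components truncated at zero; reproducibility binning
  (Poor < 0.4 ≤ Fair < 0.6 ≤ Good < 0.75 ≤ Excellent ≤ 1); and a two-sided
  Wilcoxon rank-sum test (exact by enumeration for small samples) to compare
  segmentation arms.

Everything is tidyverse-shaped: cohorts are tibbles with list-column images,
feature extraction returns long tibbles, fitted ICC objects have `tidy()` /
`glance()` methods, and reports have `autoplot()`.

## Worked example

```r
library(radstab)

cfg <- experiment_config(
  n_subjects = 12, arms = c("manual", "semiauto", "clahe"),
  observers = 1, sessions = 2, jitter_sigma = 2, seed = 42
)
run <- run_pipeline(cfg)
run
#> radstab run: 12 subjects, 1 replicate(s) x 2 session(s), arms: manual, semiauto, clahe
#> Feature stability report  [ICC(A,1)]
#>   clahe: mean ICC 1.000 +/- 0.000 over 36 features
#>   manual: mean ICC 0.614 +/- 0.313 over 36 features
#>   semiauto: mean ICC 1.000 +/- 0.000 over 36 features

glance(run$report)
#> # A tibble: 3 × 8
#>   arm      n_features mean_icc   sd_icc  Poor  Fair  Good Excellent
#>   <chr>         <int>    <dbl>    <dbl> <int> <int> <int>     <int>
#> 1 clahe            36    1     0            0     0     0        36
#> 2 manual           36    0.614 0.313       13     0     8        15
#> 3 semiauto         36    1.000 0.000160     0     0     0        36
```

Each subject's lesion is re-delineated twice (two "sessions"). The manual arm
inherits the observer's boundary jitter directly, so only 15 of 36 features
reach the Excellent bin and 13 are Poor; the two algorithmic arms re-segment
from a seed and are nearly deterministic, so their ICCs sit at 1. The pairwise
Wilcoxon p-values in `run$report$pairwise` confirm the manual arm differs from
both algorithmic arms.

Single tables work too:

```r
v <- c(0.31, 0.35, 0.52, 0.48, 0.60, 0.44, 0.55, 0.62)   # one feature, 8 subjects
set.seed(1)
tab <- cbind(session1 = v, session2 = v + rnorm(8, sd = 0.03))
icc_agreement(tab)
#> ICC(A,1) = 0.9765  [Excellent]
```

`autoplot(run$report)` draws the stacked reproducibility-group bars per arm;
`plot_icc_comparison(run$report)` shows per-feature ICC side by side;
`plot_gray_image(image, mask)` overlays a mask contour on a slice.

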