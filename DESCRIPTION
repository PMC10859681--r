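Package: radstab
Title: Radiomics Feature Stability on Enhanced and Segmented Grayscale MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the test-retest stability of radiomics features
    extracted from 2-D grayscale MRI slices under different contrast-enhancement
    and lesion-segmentation strategies. Implements contrast-limited adaptive
    histogram equalization (CLAHE) from first principles, geodesic
    active-contour level-set and region-growing segmentation, a 36-feature
    registry of gray-level co-occurrence matrix (GLCM) texture, first-order
    intensity, and shape features, and two-way ANOVA intraclass correlation
    coefficients ICC(A,1)/ICC(C,1) with reproducibility binning and Wilcoxon
    rank-sum comparisons between segmentation arms. A synthetic phantom
    generator produces diffusion-weighted-MRI-like slices with Rician noise,
    smooth bias fields, and simulated observer delineation variability, so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
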