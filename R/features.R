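#' Feature-extraction configuration
#'
#' @param glcm_levels Gray-level count for GLCM quantization; default 8.
#' @param glcm_distance Co-occurrence offset distance in pixels; default 1.
#' @param first_order_bins Histogram bin count for first-order entropy;
#'   default 64.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(glcm_levels = 8, glcm_distance = 1,
                           first_order_bins = 64) {
  if (glcm_levels < 2) abort("`glcm_levels` must be >= 2.")
  if (glcm_distance < 1) abort("`glcm_distance` must be >= 1.")
  if (first_order_bins < 2) abort("`first_order_bins` must be >= 2.")
  structure(list(glcm_levels = as.integer(glcm_levels),
                 glcm_distance = as.integer(glcm_distance),
                 first_order_bins = as.integer(first_order_bins)),
            class = "feature_config")
}

#' The canonical 36-feature registry
#'
#' 21 GLCM texture features, 6 first-order intensity features, and 9 shape
#' features, in a fixed order. The two standard homogeneity variants (inverse
#' difference and inverse difference moment) are both included.
#'
#' @return A tibble with columns `feature`, `group`, `definition`.
#' @export
feature_registry <- function() {
  tibble(
    feature = c(
      "glcm_autocorrelation", "glcm_contrast", "glcm_correlation",
      "glcm_cluster_prominence", "glcm_cluster_shade", "glcm_dissimilarity",
      "glcm_energy", "glcm_entropy", "glcm_homogeneity1", "glcm_homogeneity2",
      "glcm_maximum_probability", "glcm_sum_of_squares", "glcm_sum_average",
      "glcm_sum_variance", "glcm_sum_entropy", "glcm_difference_variance",
      "glcm_difference_entropy", "glcm_imc1", "glcm_imc2", "glcm_idn",
      "glcm_idmn",
      "fo_entropy", "fo_kurtosis", "fo_skewness", "fo_energy", "fo_variance",
      "fo_mean",
      "shape_area", "shape_major_axis_length", "shape_minor_axis_length",
      "shape_perimeter", "shape_equiv_diameter", "shape_convex_area",
      "shape_orientation", "shape_solidity", "shape_eccentricity"
    ),
    group = c(rep("glcm", 21), rep("first_order", 6), rep("shape", 9)),
    definition = c(
      "sum_ij i*j*P(i,j)",
      "sum_ij (i-j)^2 P(i,j)",
      "(sum_ij i*j*P - mu_x*mu_y) / (sd_x*sd_y)",
      "sum_ij (i+j-mu_x-mu_y)^4 P(i,j)",
      "sum_ij (i+j-mu_x-mu_y)^3 P(i,j)",
      "sum_ij |i-j| P(i,j)",
      "sum_ij P(i,j)^2",
      "-sum_ij P log2 P",
      "sum_ij P / (1+|i-j|)  (inverse difference)",
      "sum_ij P / (1+(i-j)^2)  (inverse difference moment)",
      "max_ij P(i,j)",
      "sum_ij (i-mu)^2 P(i,j)  (variance about the GLCM mean)",
      "sum_k k p_{x+y}(k)",
      "sum_k (k - sum_average)^2 p_{x+y}(k)",
      "-sum_k p_{x+y} log2 p_{x+y}",
      "sum_k (k - mu_d)^2 p_{x-y}(k)",
      "-sum_k p_{x-y} log2 p_{x-y}",
      "(HXY - HXY1) / max(HX, HY)",
      "sqrt(1 - exp(-2 (HXY2 - HXY)))",
      "sum_ij P / (1+|i-j|/N)  (inverse difference normalized)",
      "sum_ij P / (1+(i-j)^2/N^2)  (inverse difference moment normalized)",
      "histogram entropy (base 2)",
      "standardized fourth central moment (not excess)",
      "standardized third central moment",
      "sum of squared masked intensities",
      "population variance of masked intensities",
      "mean masked intensity",
      "pixel count",
      "major axis of the moment-matched ellipse",
      "minor axis of the moment-matched ellipse",
      "8-connected boundary-trace arc length (sqrt(2) diagonals)",
      "sqrt(4*area/pi)",
      "pixel count of the convex hull",
      "ellipse orientation, degrees in (-90, 90] from the row axis",
      "area / convex_area",
      "sqrt(1 - (minor/major)^2)"
    )
  )
}

#' Quantize masked intensities to discrete gray levels
#'
#' Bins the masked intensities into `n_levels` equal-width bins spanning the
#' `[min, max]` range of the masked region; a constant region maps to level 0.
#'
#' @param image Numeric matrix.
#' @param mask Non-empty logical matrix.
#' @param n_levels Number of gray levels (>= 2).
#' @return Integer matrix of levels `0 .. n_levels-1` (NA outside the mask).
#' @export
quantize_gray <- function(image, mask, n_levels = 8) {
  assert_image(image)
  assert_mask(mask)
  assert_same_dim(image, mask)
  if (n_levels < 2) abort("`n_levels` must be >= 2.")
  v <- image[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (diff(rng) < .Machine$double.eps) {
    q[mask] <- 0L
  } else {
    lev <- floor((v - rng[1]) / diff(rng) * n_levels)
    q[mask] <- as.integer(pmin(lev, n_levels - 1L))
  }
  attr(q, "n_levels") <- as.integer(n_levels)
  q
}

# Pixel offset for a GLCM angle, image convention (rows increase downward):
# 0 deg = (0, d), 45 = (-d, d), 90 = (-d, 0), 135 = (-d, -d).
glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    abort("`angle` must be one of 0, 45, 90, 135 degrees.")
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized level pairs at the given offset with both
#' pixels inside the mask, accumulates symmetrically (each pair contributes in
#' both directions), and normalizes to sum 1.
#'
#' @param quantized Integer matrix of levels from [quantize_gray()].
#' @param mask Logical matrix; pairs must have both endpoints in the mask.
#' @param distance Offset distance in pixels (>= 1).
#' @param angle One of 0, 45, 90, 135 degrees.
#' @return An `N x N` matrix of joint probabilities summing to 1, with
#'   attribute `n_levels`.
#' @export
glcm <- function(quantized, mask, distance = 1, angle = 0) {
  if (distance < 1) abort("`distance` must be >= 1.")
  n_levels <- attr(quantized, "n_levels") %||%
    (max(quantized, na.rm = TRUE) + 1L)
  assert_mask(mask)
  off <- glcm_offset(as.integer(distance), angle)
  nr <- nrow(quantized); nc <- ncol(quantized)
  idx <- which(mask, arr.ind = TRUE)
  r2 <- idx[, 1] + off[1]; c2 <- idx[, 2] + off[2]
  ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
  ok[ok] <- mask[cbind(r2[ok], c2[ok])]
  if (!any(ok)) abort("no valid pixel pairs at this offset.")
  a <- quantized[idx[ok, , drop = FALSE]]
  b <- quantized[cbind(r2[ok], c2[ok])]
  P <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a, levels = 0:(n_levels - 1L)),
               factor(b, levels = 0:(n_levels - 1L)))
  P <- unclass(tab) + t(unclass(tab))  # symmetric accumulation
  P <- P / sum(P)
  dimnames(P) <- NULL
  attr(P, "n_levels") <- as.integer(n_levels)
  P
}

# log2 with the 0*log(0) = 0 convention.
xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

#' The 21 GLCM texture features
#'
#' Standard Haralick-family definitions with levels indexed `1..N`, entropy in
#' bits (`0*log 0 = 0`), and the two homogeneity variants (inverse difference,
#' inverse difference moment). Degenerate denominators (zero marginal variance
#' for correlation, `max(HX, HY) = 0` for the first information measure of
#' correlation) return 0 by convention so feature vectors stay NaN-free.
#'
#' @param P Normalized co-occurrence matrix (entries sum to 1).
#' @return Named numeric vector of 21 features.
#' @export
glcm_features <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) abort("`P` must be a square matrix.")
  if (abs(sum(P) - 1) > 1e-8) abort("`P` is not normalized: entries must sum to 1.")
  if (any(P < 0)) abort("`P` has negative entries.")
  N <- nrow(P)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)

  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(N) * px); mu_y <- sum(seq_len(N) * py)
  sd_x <- sqrt(sum((seq_len(N) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(N) - mu_y)^2 * py))

  # Sum and difference marginals p_{x+y}(k), k = 2..2N, and p_{x-y}(k), k = 0..N-1.
  k_sum <- 2:(2 * N)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  k_diff <- 0:(N - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))

  contrast <- sum((i - j)^2 * P)
  dissimilarity <- sum(abs(i - j) * P)
  energy <- sum(P^2)
  entropy <- -sum(P * xlog2(P))
  autocorrelation <- sum(i * j * P)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (autocorrelation - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  cluster_shade <- sum((i + j - mu_x - mu_y)^3 * P)
  cluster_prominence <- sum((i + j - mu_x - mu_y)^4 * P)
  homogeneity1 <- sum(P / (1 + abs(i - j)))
  homogeneity2 <- sum(P / (1 + (i - j)^2))
  maximum_probability <- max(P)
  mu_glcm <- sum(i * P)  # == mean of the symmetric marginal
  sum_of_squares <- sum((i - mu_glcm)^2 * P)
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- -sum(p_sum * xlog2(p_sum))
  mu_d <- sum(k_diff * p_diff)
  difference_variance <- sum((k_diff - mu_d)^2 * p_diff)
  difference_entropy <- -sum(p_diff * xlog2(p_diff))

  hx <- -sum(px * xlog2(px)); hy <- -sum(py * xlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  idn <- sum(P / (1 + abs(i - j) / N))
  idmn <- sum(P / (1 + (i - j)^2 / N^2))

  c(glcm_autocorrelation = autocorrelation, glcm_contrast = contrast,
    glcm_correlation = correlation, glcm_cluster_prominence = cluster_prominence,
    glcm_cluster_shade = cluster_shade, glcm_dissimilarity = dissimilarity,
    glcm_energy = energy, glcm_entropy = entropy,
    glcm_homogeneity1 = homogeneity1, glcm_homogeneity2 = homogeneity2,
    glcm_maximum_probability = maximum_probability,
    glcm_sum_of_squares = sum_of_squares, glcm_sum_average = sum_average,
    glcm_sum_variance = sum_variance, glcm_sum_entropy = sum_entropy,
    glcm_difference_variance = difference_variance,
    glcm_difference_entropy = difference_entropy,
    glcm_imc1 = imc1, glcm_imc2 = imc2, glcm_idn = idn, glcm_idmn = idmn)
}

#' First-order intensity features of a masked region
#'
#' Mean, population variance, skewness and (non-excess) kurtosis as
#' standardized central moments, energy as the sum of squared raw intensities,
#' and histogram entropy (base 2, `n_bins` equal-width bins over the masked
#' range). A zero-variance region returns skewness and kurtosis of 0 and
#' entropy 0 by convention.
#'
#' @param image Numeric matrix.
#' @param mask Non-empty logical matrix.
#' @param n_bins Histogram bin count for entropy.
#' @return Named numeric vector of 6 features.
#' @export
first_order_features <- function(image, mask, n_bins = 64) {
  assert_image(image)
  assert_mask(mask)
  assert_same_dim(image, mask)
  v <- image[mask]
  n <- length(v)
  m <- mean(v)
  s2 <- sum((v - m)^2) / n
  if (s2 > 0) {
    skew <- sum((v - m)^3) / n / s2^1.5
    kurt <- sum((v - m)^4) / n / s2^2
    h <- tabulate(bin_index((v - min(v)) / diff(range(v)), n_bins), nbins = n_bins)
    p <- h / n
    ent <- -sum(p * xlog2(p))
  } else {
    skew <- 0; kurt <- 0; ent <- 0
  }
  c(fo_entropy = ent, fo_kurtosis = kurt, fo_skewness = skew,
    fo_energy = sum(v^2), fo_variance = s2, fo_mean = m)
}

#' Shape features of a binary mask
#'
#' Area is the pixel count; axis lengths, orientation, and eccentricity come
#' from the ellipse with matching normalized second central moments (with the
#' 1/12-pixel correction); equivalent diameter is `sqrt(4*area/pi)`; convex
#' area and solidity use the pixel-center convex hull; perimeter is the
#' 8-connected boundary-trace arc length with `sqrt(2)` diagonal steps.
#' Orientation is reported in degrees in (-90, 90\], measured from the row
#' axis toward the column axis.
#'
#' @param mask Non-empty logical matrix.
#' @return Named numeric vector of 9 features.
#' @export
shape_features <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  r <- idx[, 1]; c_ <- idx[, 2]
  mr <- mean(r); mc <- mean(c_)
  # Normalized second central moments with the pixel-extent correction.
  urr <- sum((r - mr)^2) / area + 1 / 12
  ucc <- sum((c_ - mc)^2) / area + 1 / 12
  urc <- sum((r - mr) * (c_ - mc)) / area
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  major <- 2 * sqrt(2) * sqrt(urr + ucc + common)
  minor <- 2 * sqrt(2) * sqrt(pmax(urr + ucc - common, 0))
  eccentricity <- sqrt(pmax(1 - (minor / major)^2, 0))
  orientation <- if (common < .Machine$double.eps) 0 else {
    deg <- atan2(2 * urc, urr - ucc) / 2 * 180 / pi
    if (deg <= -90) deg + 180 else if (deg > 90) deg - 180 else deg
  }

  hull <- grDevices::chull(r, c_)
  hr <- r[hull]; hc <- c_[hull]
  convex_area <- if (length(hull) < 3) area else {
    pts <- which(matrix(TRUE, nrow(mask), ncol(mask)), arr.ind = TRUE)
    inside <- point_in_convex_polygon(pts[, 1], pts[, 2], hr, hc)
    sum(inside)
  }
  convex_area <- max(convex_area, area)

  perimeter <- mask_perimeter(mask)

  c(shape_area = area,
    shape_major_axis_length = major,
    shape_minor_axis_length = minor,
    shape_perimeter = perimeter,
    shape_equiv_diameter = sqrt(4 * area / pi),
    shape_convex_area = convex_area,
    shape_orientation = orientation,
    shape_solidity = area / convex_area,
    shape_eccentricity = eccentricity)
}

# Vectorized point-in-convex-polygon test (hull vertices in chull order).
point_in_convex_polygon <- function(pr, pc, hr, hc) {
  n <- length(hr)
  inside <- rep(TRUE, length(pr))
  sgn <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cross <- (hr[k2] - hr[k]) * (pc - hc[k]) - (hc[k2] - hc[k]) * (pr - hr[k])
    if (sgn == 0) {
      nz <- cross[abs(cross) > 1e-9]
      if (length(nz)) sgn <- sign(nz[1])
    }
    inside <- inside & (sgn * cross >= -1e-9)
  }
  inside
}

# Boundary-trace perimeter: Moore contour per connected component, step
# lengths 1 (axial) or sqrt(2) (diagonal), closed.
mask_perimeter <- function(mask) {
  if (sum(mask) == 1) return(0)
  contours <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))
  total <- 0
  for (cc in contours) {
    if (nrow(cc) < 2) next
    nxt <- rbind(cc[-1, , drop = FALSE], cc[1, , drop = FALSE])
    total <- total + sum(sqrt(rowSums((nxt - cc)^2)))
  }
  total
}

#' Extract the full 36-feature registry from an (image, mask) pair
#'
#' GLCM features are computed at the configured distance for the four standard
#' angles (0, 45, 90, 135 degrees) and averaged; first-order features use the
#' raw masked intensities; shape features use the mask alone. The result always
#' has exactly 36 finite entries in registry order.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param mask Non-empty logical matrix, same dimension.
#' @param config A [feature_config()].
#' @return A tibble with columns `feature`, `group`, `value` (36 rows, fixed
#'   registry order).
#' @export
extract_features <- function(image, mask, config = feature_config()) {
  assert_image(image)
  assert_mask(mask)
  assert_same_dim(image, mask)
  stopifnot(inherits(config, "feature_config"))
  q <- quantize_gray(image, mask, config$glcm_levels)
  angles <- c(0, 45, 90, 135)
  gl <- rowMeans(vapply(
    angles,
    function(a) glcm_features(glcm(q, mask, config$glcm_distance, a)),
    numeric(21)
  ))
  fo <- first_order_features(image, mask, config$first_order_bins)
  sh <- shape_features(mask)
  vals <- c(gl, fo, sh)
  reg <- feature_registry()
  stopifnot(identical(names(vals), reg$feature))
  if (any(!is.finite(vals))) {
    abort(paste0("non-finite feature value(s): ",
                 paste(names(vals)[!is.finite(vals)], collapse = ", ")))
  }
  tibble(feature = reg$feature, group = reg$group, value = unname(vals))
}
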