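test_that("quantization covers degenerate and two-level cases", {
  img <- matrix(0.5, 8, 8); mask <- matrix(TRUE, 8, 8)
  q <- quantize_gray(img, mask, 8)
  expect_true(all(q[mask] == 0))

  two <- matrix(rep(c(0, 1), 32), 8, 8)
  q2 <- quantize_gray(two, mask, 2)
  expect_setequal(unique(as.vector(q2[mask])), c(0L, 1L))
  expect_identical(q2[mask] == 1L, two[mask] == 1)

  expect_error(quantize_gray(img, matrix(FALSE, 8, 8), 8), "empty")
  expect_error(quantize_gray(img, mask, 1), "n_levels")
})

test_that("uniform intensities quantize to an approximately uniform level histogram", {
  withr::with_seed(3, {
    img <- matrix(runif(10000), 100, 100)
    mask <- matrix(TRUE, 100, 100)
    q <- quantize_gray(img, mask, 8)
    tab <- tabulate(q[mask] + 1L, nbins = 8)
    expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  })
})

test_that("GLCM matches hand counts and the pair-enumeration oracle", {
  img <- rbind(c(0, 0), c(1, 1))
  mask <- matrix(TRUE, 2, 2)
  q <- quantize_gray(img, mask, 2)
  P <- glcm(q, mask, 1, 0)
  expect_equal(unclass(P)[1:2, 1:2], rbind(c(0.5, 0), c(0, 0.5)),
               ignore_attr = TRUE)

  const <- quantize_gray(matrix(0.4, 4, 4), matrix(TRUE, 4, 4), 8)
  Pc <- glcm(const, matrix(TRUE, 4, 4), 1, 0)
  expect_equal(Pc[1, 1], 1)
  expect_equal(sum(Pc), 1)

  withr::with_seed(9, {
    offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1))
    for (trial in 1:10) {
      img <- matrix(runif(256), 16, 16)
      mask <- matrix(runif(256) > 0.2, 16, 16)
      q <- quantize_gray(img, mask, 8)
      for (ang in c(0, 45, 90, 135)) {
        off <- offsets[[as.character(ang)]]
        expect_equal(unclass(glcm(q, mask, 1, ang)),
                     oracle_glcm(q, mask, off[1], off[2], 8),
                     ignore_attr = TRUE, tolerance = 1e-14)
      }
    }
  })
  expect_error(glcm(q, mask, 1, 30), "angle")
  one <- matrix(TRUE, 1, 1)
  expect_error(glcm(matrix(0L, 1, 1), one, 1, 0), "no valid pixel pairs")
})

test_that("GLCM features obey closed forms on diagonal and uniform matrices", {
  N <- 8
  Pd <- diag(N) / N
  f <- glcm_features(Pd)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_dissimilarity"]], 0)
  expect_equal(f[["glcm_homogeneity1"]], 1)
  expect_equal(f[["glcm_homogeneity2"]], 1)
  expect_equal(f[["glcm_energy"]], 1 / N)

  Pu <- matrix(1 / N^2, N, N)
  fu <- glcm_features(Pu)
  expect_equal(fu[["glcm_entropy"]], 2 * log2(N))
  expect_equal(fu[["glcm_maximum_probability"]], 1 / N^2)

  expect_error(glcm_features(matrix(1, 4, 4)), "not normalized")
})

test_that("all 21 GLCM features match the textbook oracle on random matrices", {
  withr::with_seed(17, {
    for (trial in 1:100) {
      P <- random_glcm(8)
      got <- glcm_features(P)
      want <- oracle_glcm_features(P)
      expect_equal(got, want[names(got)], tolerance = 1e-9)
    }
  })
})

test_that("first-order features follow their conventions and the direct oracle", {
  mask <- matrix(TRUE, 10, 10)
  f <- first_order_features(matrix(0.42, 10, 10), mask)
  expect_equal(unname(f), c(0, 0, 0, 100 * 0.42^2, 0, 0.42))

  two <- matrix(rep(c(0, 1), 50), 10, 10)  # {0,1} halves, scaled to {0,2}*0.5
  img2 <- matrix(rep(c(0, 2), 50), 10, 10) / 2  # values 0, 1 in [0,1]
  f2 <- first_order_features(img2, mask)
  expect_equal(f2[["fo_mean"]], 0.5)
  expect_equal(f2[["fo_variance"]], 0.25)
  expect_equal(f2[["fo_skewness"]], 0)
  expect_equal(f2[["fo_entropy"]], 1)

  withr::with_seed(23, {
    for (trial in 1:20) {
      img <- matrix(runif(400), 20, 20)
      mk <- matrix(runif(400) > 0.3, 20, 20)
      v <- img[mk]; n <- length(v); m <- mean(v)
      s2 <- sum((v - m)^2) / n
      f <- first_order_features(img, mk, n_bins = 32)
      expect_equal(f[["fo_mean"]], m, tolerance = 1e-10)
      expect_equal(f[["fo_variance"]], s2, tolerance = 1e-10)
      expect_equal(f[["fo_skewness"]], sum((v - m)^3) / n / s2^1.5, tolerance = 1e-10)
      expect_equal(f[["fo_kurtosis"]], sum((v - m)^4) / n / s2^2, tolerance = 1e-10)
      expect_equal(f[["fo_energy"]], sum(v^2), tolerance = 1e-10)
      b <- pmin(floor((v - min(v)) / (max(v) - min(v)) * 32) + 1, 32)
      p <- tabulate(b, 32) / n; p <- p[p > 0]
      expect_equal(f[["fo_entropy"]], -sum(p * log2(p)), tolerance = 1e-10)
    }
  })
  expect_error(first_order_features(matrix(0.1, 4, 4), matrix(FALSE, 4, 4)), "empty")
})

test_that("shape features reproduce closed forms on squares and ellipses", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  f <- shape_features(sq)
  expect_equal(f[["shape_area"]], 100)
  expect_equal(f[["shape_solidity"]], 1)
  expect_equal(f[["shape_equiv_diameter"]], sqrt(400 / pi), tolerance = 1e-12)
  expect_equal(f[["shape_convex_area"]], 100)
  expect_equal(f[["shape_perimeter"]], 36)
  expect_equal(f[["shape_eccentricity"]], 0, tolerance = 1e-9)

  sp <- phantom_spec(height = 96, width = 96, lesion_axes = c(20, 10),
                     lesion_rotation = 0, noise_sigma = 0, bias_amplitude = 0)
  el <- generate_phantom(sp)$mask
  fe <- shape_features(el)
  expect_equal(fe[["shape_eccentricity"]], sqrt(1 - 0.25), tolerance = 0.02)
  expect_lt(abs(fe[["shape_orientation"]]), 2)
  expect_equal(fe[["shape_major_axis_length"]], 40, tolerance = 0.05 * 40)
  expect_error(shape_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("shape features transform correctly under 90-degree rotation", {
  sp <- phantom_spec(height = 96, width = 96, lesion_axes = c(18, 9),
                     lesion_rotation = 25, noise_sigma = 0, bias_amplitude = 0)
  mask <- generate_phantom(sp)$mask
  rot <- t(mask)[ncol(mask):1, ]  # 90-degree rotation
  f0 <- shape_features(mask); f90 <- shape_features(rot)
  for (nm in c("shape_area", "shape_perimeter", "shape_solidity",
               "shape_equiv_diameter", "shape_eccentricity")) {
    expect_equal(f90[[nm]], f0[[nm]], tolerance = 0.01)
  }
  expect_equal(f90[["shape_major_axis_length"]], f0[["shape_major_axis_length"]],
               tolerance = 0.01)
  expect_equal(f90[["shape_minor_axis_length"]], f0[["shape_minor_axis_length"]],
               tolerance = 0.01)
  d_or <- (f90[["shape_orientation"]] - f0[["shape_orientation"]]) %% 180
  expect_lt(min(abs(d_or - 90), abs(d_or - 90 + 180), abs(d_or - 90 - 180)), 2)
})

test_that("the registry vector is complete, ordered, invariant, deterministic", {
  sp <- phantom_spec(noise_sigma = 0.04, bias_amplitude = 0.1, seed = 6)
  ph <- generate_phantom(sp)
  fv <- extract_features(ph$image, ph$mask)
  expect_equal(nrow(fv), 36)
  expect_identical(fv$feature, feature_registry()$feature)
  expect_true(all(is.finite(fv$value)))
  expect_identical(extract_features(ph$image, ph$mask), fv)

  # joint translation of image and mask leaves every feature unchanged
  shift_rc <- function(m, dr, dc) {
    out <- matrix(if (is.logical(m)) FALSE else 0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  sp_small <- phantom_spec(height = 96, width = 96, lesion_center = c(40, 40),
                           lesion_axes = c(14, 10), noise_sigma = 0.04, seed = 6)
  ph2 <- generate_phantom(sp_small)
  fv_shift <- extract_features(shift_rc(ph2$image, 3, 7), shift_rc(ph2$mask, 3, 7))
  fv_orig <- extract_features(ph2$image, ph2$mask)
  # shape orientation/centroid-free registry: all but nothing should change
  expect_equal(fv_shift$value, fv_orig$value, tolerance = 1e-12)
})

test_that("GLCM texture is invariant to a constant intensity shift", {
  withr::with_seed(31, {
    img <- matrix(runif(900, 0, 0.8), 30, 30)
    mask <- mk_disk(30, 12)
    a <- extract_features(img, mask)
    b <- extract_features(img + 0.2, mask)
    for (nm in c("glcm_contrast", "glcm_dissimilarity", "glcm_entropy")) {
      expect_equal(b$value[b$feature == nm], a$value[a$feature == nm],
                   tolerance = 1e-10)
    }
  })
})

test_that("area scales quadratically with lesion radius", {
  a1 <- shape_features(mk_disk(96, 10))[["shape_area"]]
  a2 <- shape_features(mk_disk(96, 20))[["shape_area"]]
  expect_equal(a2 / a1, 4, tolerance = 0.03)
})
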