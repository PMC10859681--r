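test_that("edge indicator is 1 on flat images and decreases with edge strength", {
  expect_equal(edge_indicator(matrix(0.5, 20, 20), 1.5), matrix(1, 20, 20))
  soft <- matrix(rep(seq(0, 0.2, length.out = 20), each = 20), 20, 20)
  sharp <- matrix(rep(c(rep(0, 10), rep(0.8, 10)), each = 20), 20, 20)
  expect_lt(min(edge_indicator(sharp, 1)), min(edge_indicator(soft, 1)))
  expect_error(edge_indicator(matrix(0.5, 5, 5), -1), "edge_sigma")
})

test_that("edge indicator matches the closed form on a step edge", {
  img <- matrix(rep(c(rep(0.2, 16), rep(0.9, 16)), each = 32), 32, 32)
  expect_lt(max(abs(edge_indicator(img, 1) - oracle_edge_indicator(img, 1))),
            1e-10)
  expect_lt(max(abs(edge_indicator(img, 2, gain = 5) -
                    oracle_edge_indicator(img, 2, gain = 5))),
            1e-10)
})

test_that("curvature reproduces closed forms", {
  n <- 64
  x <- matrix(seq_len(n), n, n) - (n + 1) / 2
  y <- t(x)
  u <- sqrt(x^2 + y^2) - 15
  k <- curvature(u)
  r <- sqrt(x^2 + y^2)
  for (r0 in c(8, 12, 20)) {
    sel <- abs(r - r0) < 0.5
    expect_equal(mean(k[sel]), 1 / r0, tolerance = 0.05)
  }
  expect_equal(curvature(x)[5:60, 5:60], matrix(0, 56, 56))
  expect_error(curvature(matrix(1, 2, 2)), "3 x 3")
})

test_that("curvature matches the analytic formula on random quadratic fields", {
  # Central differences are exact for quadratics, so the analytic
  # kappa = (uxx uy^2 - 2 ux uy uxy + uyy ux^2) / |grad u|^3 must agree to
  # machine precision away from critical points.
  n <- 32
  x <- matrix(seq_len(n), n, n) / n
  y <- t(x)
  withr::with_seed(13, {
    for (trial in 1:10) {
      cf <- rnorm(5)
      u <- cf[1] * x^2 + cf[2] * y^2 + cf[3] * x * y + cf[4] * x + cf[5] * y
      ux <- (2 * cf[1] * x + cf[3] * y + cf[4]) / n
      uy <- (2 * cf[2] * y + cf[3] * x + cf[5]) / n
      uxx <- 2 * cf[1] / n^2; uyy <- 2 * cf[2] / n^2; uxy <- cf[3] / n^2
      g2 <- ux^2 + uy^2
      analytic <- (uxx * uy^2 - 2 * ux * uy * uxy + uyy * ux^2) / g2^1.5
      interior <- matrix(FALSE, n, n); interior[2:(n - 1), 2:(n - 1)] <- TRUE
      ok <- interior & g2 > 1e-4
      expect_lt(max(abs(curvature(u)[ok] - analytic[ok])), 1e-6)
    }
  })
})

test_that("balloon sign drives growth/shrinkage on featureless images", {
  flat <- matrix(0.5, 96, 96)
  init <- mk_disk(96, 8)
  areas_grow <- vapply(c(10, 30, 60), function(it) {
    sum(evolve_level_set(flat, init, snake_params(balloon = 1, iterations = it)))
  }, numeric(1))
  expect_true(all(diff(areas_grow) > 0))
  expect_gt(areas_grow[1], sum(init))

  areas_shrink <- vapply(c(40, 80), function(it) {
    sum(evolve_level_set(flat, mk_disk(96, 20),
                         snake_params(balloon = 0, iterations = it, dt = 0.1,
                                      reinit_every = 0)))
  }, numeric(1))
  expect_lt(areas_shrink[1], sum(mk_disk(96, 20)))
  expect_lt(areas_shrink[2], areas_shrink[1])
})

test_that("pure curvature flow shrinks a disk at rate 1/r", {
  # r(t)^2 = r0^2 - 2t for mean-curvature motion of a circle.
  flat <- matrix(0.5, 128, 128)
  init <- mk_disk(128, 20)
  t_end <- 40
  out <- evolve_level_set(flat, init,
                          snake_params(balloon = 0, iterations = 800, dt = 0.05,
                                       reinit_every = 100))
  r_measured <- sqrt(sum(out) / pi)
  r_pred <- sqrt(20^2 - 2 * t_end)
  shrink_measured <- 20 - r_measured
  shrink_pred <- 20 - r_pred
  expect_lt(abs(shrink_measured - shrink_pred) / shrink_pred, 0.05)
})

test_that("a front initialized on a strong closed edge stays put", {
  sp <- phantom_spec(height = 96, width = 96, lesion_axes = c(20, 16),
                     lesion_intensity = 1, background_intensity = 0,
                     noise_sigma = 0, bias_amplitude = 0)
  ph <- generate_phantom(sp)
  out <- evolve_level_set(ph$image, ph$mask,
                          snake_params(balloon = -0.5, iterations = 100,
                                       edge_gain = 10))
  moved <- xor(out, ph$mask)
  if (any(moved)) {
    bd <- abs(radstab:::signed_distance(ph$mask)[moved])
    expect_lte(max(bd), 1)
  }
  expect_gte(dice(out, ph$mask), 0.98)
})

test_that("level-set recovery on noiseless phantoms reaches high Dice", {
  geo <- random_phantom_geometry(4, seed = 5)
  for (g in geo) {
    ph <- generate_phantom(phantom_spec(96, 96, g$ctr, c(g$a, g$b), g$rot,
                                        1, 0, 0, 0, seed = 1))
    init <- radstab:::mask_dilate(ph$mask, 5)
    out <- evolve_level_set(ph$image, init,
                            snake_params(balloon = -1, iterations = 100,
                                         edge_gain = 10))
    expect_gte(dice(out, ph$mask), 0.95)
  }
})

test_that("level-set evolution is deterministic, errors on empty init, flags collapse", {
  sp <- phantom_spec(noise_sigma = 0.05, seed = 2)
  ph <- generate_phantom(sp)
  p <- snake_params(iterations = 20)
  expect_identical(evolve_level_set(ph$image, ph$mask, p),
                   evolve_level_set(ph$image, ph$mask, p))
  expect_error(evolve_level_set(ph$image, matrix(FALSE, 96, 96), p), "empty")
  flat <- matrix(0.5, 48, 48)
  expect_warning(
    collapsed <- evolve_level_set(flat, mk_disk(48, 3),
                                  snake_params(balloon = -1, iterations = 100)),
    "collapsed"
  )
  expect_false(any(collapsed))
  expect_true(attr(collapsed, "collapsed"))
})

test_that("region growing matches flood-fill semantics", {
  flat <- matrix(0.5, 16, 16)
  expect_true(all(region_grow(flat, c(8, 8), 0.01)))

  img <- matrix(0.5, 9, 9); img[5, 5] <- 0.9
  expect_equal(sum(region_grow(img, c(5, 5), 0)), 1)

  two <- matrix(0.2, 20, 20); two[, 11:20] <- 0.8
  grown <- region_grow(two, c(4, 4), 0.1)
  expect_identical(grown, two < 0.5)
  grown_b <- region_grow(two, c(4, 15), 0.1)
  expect_identical(grown_b, two > 0.5)

  # 4-connectivity: diagonal-only bridges must not leak.
  diag_img <- matrix(0, 5, 5); diag_img[cbind(1:5, 1:5)] <- 1
  got <- region_grow(diag_img, c(3, 3), 0.1)
  expect_equal(sum(got), 1)

  expect_error(region_grow(flat, c(0, 5), 0.1), "inside the image")
  expect_error(region_grow(flat, c(5, 5), -1), "tol")
})

test_that("manual masks load from PNG and NIfTI with validation", {
  sp <- phantom_spec(noise_sigma = 0, bias_amplitude = 0)
  ph <- generate_phantom(sp)
  png_path <- withr::local_tempfile(fileext = ".png")
  write_gray_image(ph$mask, png_path)
  mk <- load_manual_mask(png_path, ph$image)
  expect_identical(mk, ph$mask)

  nii_path <- withr::local_tempfile(fileext = ".nii.gz")
  write_gray_image(ph$mask, nii_path)
  expect_identical(load_manual_mask(nii_path), ph$mask)

  zero_path <- withr::local_tempfile(fileext = ".png")
  write_gray_image(matrix(FALSE, 8, 8), zero_path)
  expect_error(load_manual_mask(zero_path), "empty mask")

  small <- matrix(0.5, 10, 10)
  expect_error(load_manual_mask(png_path, small), "96")
})

test_that("contour energy rewards strong edges and penalizes stretching", {
  sp <- phantom_spec(height = 64, width = 64, lesion_center = c(32, 32),
                     lesion_axes = c(15, 15), lesion_intensity = 1,
                     background_intensity = 0, noise_sigma = 0,
                     bias_amplitude = 0)
  ph <- generate_phantom(sp)
  circle <- function(r) {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    cbind(32 + r * cos(th), 32 + r * sin(th))
  }
  on_edge <- contour_energy(ph$image, circle(15), alpha = 0, gamma = 1)
  off_edge <- contour_energy(ph$image, circle(8), alpha = 0, gamma = 1)
  expect_lt(on_edge, off_edge)
  # internal (elastic) energy grows with contour length
  expect_lt(contour_energy(ph$image, circle(8), alpha = 1, gamma = 0),
            contour_energy(ph$image, circle(15), alpha = 1, gamma = 0))
  expect_error(contour_energy(ph$image, circle(8), alpha = -1), "weights")
})
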