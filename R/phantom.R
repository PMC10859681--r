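#' Specification for a synthetic DWI-like phantom slice
#'
#' Describes a 2-D axial slice containing a single bright elliptical lesion
#' (restricted diffusion appears hyperintense on DWI) on a darker background,
#' corrupted by a smooth multiplicative bias field and Rician noise — the
#' magnitude-image noise model of MRI. All intensities are normalized to
#' \[0, 1\].
#'
#' @param height,width Image size in pixels.
#' @param lesion_center Numeric length-2 `(row, col)` of the lesion center.
#' @param lesion_axes Numeric length-2 `(a, b)` semi-axis lengths in pixels.
#' @param lesion_rotation Lesion rotation in degrees (counter-clockwise from
#'   the row axis).
#' @param lesion_intensity,background_intensity Noise-free intensities of the
#'   lesion and background; `0 <= background < lesion <= 1`.
#' @param noise_sigma Rician scale parameter, in normalized intensity units.
#' @param bias_amplitude Peak-to-peak fraction of the multiplicative
#'   inhomogeneity field (0 disables it).
#' @param seed Integer RNG seed; identical specs produce bit-identical output.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(noise_sigma = 0.05, seed = 7)
#' ph <- generate_phantom(spec)
#' dim(ph$image)
#' @export
phantom_spec <- function(height = 96, width = 96,
                         lesion_center = c(height / 2, width / 2),
                         lesion_axes = c(18, 12),
                         lesion_rotation = 0,
                         lesion_intensity = 0.85,
                         background_intensity = 0.25,
                         noise_sigma = 0.05,
                         bias_amplitude = 0.2,
                         seed = 1L) {
  spec <- structure(
    list(
      height = as.integer(height), width = as.integer(width),
      lesion_center = as.numeric(lesion_center),
      lesion_axes = as.numeric(lesion_axes),
      lesion_rotation = as.numeric(lesion_rotation),
      lesion_intensity = as.numeric(lesion_intensity),
      background_intensity = as.numeric(background_intensity),
      noise_sigma = as.numeric(noise_sigma),
      bias_amplitude = as.numeric(bias_amplitude),
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (height < 4 || width < 4) abort("phantom must be at least 4 x 4 pixels.")
    if (!(background_intensity >= 0 && background_intensity < lesion_intensity &&
          lesion_intensity <= 1)) {
      abort("need 0 <= background_intensity < lesion_intensity <= 1.")
    }
    if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
    if (bias_amplitude < 0) abort("`bias_amplitude` must be >= 0.")
    if (any(lesion_axes <= 0)) abort("`lesion_axes` must be positive.")
    # Rotated-ellipse bounding half-widths along rows/cols.
    th <- lesion_rotation * pi / 180
    half_r <- sqrt((lesion_axes[1] * cos(th))^2 + (lesion_axes[2] * sin(th))^2)
    half_c <- sqrt((lesion_axes[1] * sin(th))^2 + (lesion_axes[2] * cos(th))^2)
    if (lesion_center[1] - half_r < 1 || lesion_center[1] + half_r > height ||
        lesion_center[2] - half_c < 1 || lesion_center[2] + half_c > width) {
      abort("lesion ellipse extends outside the image bounds.")
    }
  })
  spec
}

# Rasterize the spec's ellipse at pixel centers.
rasterize_ellipse <- function(spec) {
  r <- matrix(seq_len(spec$height), spec$height, spec$width)
  c_ <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  th <- spec$lesion_rotation * pi / 180
  dr <- r - spec$lesion_center[1]
  dc <- c_ - spec$lesion_center[2]
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  (u / spec$lesion_axes[1])^2 + (v / spec$lesion_axes[2])^2 <= 1
}

# Smooth multiplicative bias field 1 + amplitude * p(x, y), where p is a
# seeded low-order 2-D polynomial rescaled to [-1/2, 1/2].
bias_field <- function(spec) {
  if (spec$bias_amplitude == 0) {
    return(matrix(1, spec$height, spec$width))
  }
  coef <- with_seed_(derive_seed(spec$seed, "bias"), rnorm(5))
  x <- matrix(seq(-1, 1, length.out = spec$height), spec$height, spec$width)
  y <- matrix(seq(-1, 1, length.out = spec$width), spec$height, spec$width,
              byrow = TRUE)
  p <- coef[1] * x + coef[2] * y + coef[3] * x * y + coef[4] * x^2 + coef[5] * y^2
  rng <- range(p)
  if (diff(rng) < .Machine$double.eps) {
    p[] <- 0
  } else {
    p <- (p - rng[1]) / diff(rng) - 0.5
  }
  1 + spec$bias_amplitude * p
}

#' Generate a synthetic phantom slice and its ground-truth lesion mask
#'
#' Builds `image = bias_field x piecewise intensity`, then applies Rician
#' noise: `sqrt((s + g1)^2 + g2^2)` with `g1, g2` independent zero-mean
#' Gaussians of standard deviation `noise_sigma` (the standard magnitude-MRI
#' model; Rayleigh where the signal is zero). Output is clipped to \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @return A list with class `phantom`: `image` (numeric matrix in \[0,1\]),
#'   `mask` (logical matrix, the rasterized ellipse), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  mask <- rasterize_ellipse(spec)
  signal <- matrix(spec$background_intensity, spec$height, spec$width)
  signal[mask] <- spec$lesion_intensity
  signal <- signal * bias_field(spec)
  if (spec$noise_sigma > 0) {
    n <- length(signal)
    g <- with_seed_(derive_seed(spec$seed, "noise"),
                    matrix(rnorm(2 * n, sd = spec$noise_sigma), ncol = 2))
    signal <- sqrt((signal + g[, 1])^2 + g[, 2]^2)
    dim(signal) <- c(spec$height, spec$width)
  }
  structure(list(image = pmin(signal, 1), mask = mask, spec = spec),
            class = "phantom")
}

#' Model of repeat-delineation variability for one observer
#'
#' Emulates an observer re-drawing a lesion boundary: the boundary is displaced
#' radially by a smooth angular noise field, producing spatially correlated
#' delineation errors of controllable magnitude.
#'
#' @param boundary_jitter_sigma Standard deviation of the radial boundary
#'   displacement, in pixels. `0` reproduces the input mask exactly.
#' @param smoothness Correlation length of the angular displacement field, in
#'   degrees of arc.
#' @param seed Integer RNG seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(boundary_jitter_sigma = 2, smoothness = 30,
                           seed = 1L) {
  if (boundary_jitter_sigma < 0) abort("`boundary_jitter_sigma` must be >= 0.")
  if (smoothness <= 0) abort("`smoothness` must be > 0.")
  structure(
    list(boundary_jitter_sigma = as.numeric(boundary_jitter_sigma),
         smoothness = as.numeric(smoothness), seed = as.integer(seed)),
    class = "observer_model"
  )
}

#' Simulate a repeat manual delineation of a lesion mask
#'
#' Samples radial displacements at 64 equally spaced boundary angles, smooths
#' them with a periodic Gaussian kernel (renormalized so the marginal standard
#' deviation stays at `boundary_jitter_sigma`), and re-rasterizes the displaced
#' boundary about the mask centroid. The mask is assumed star-shaped about its
#' centroid (true for the phantom ellipses).
#'
#' @param mask Non-empty logical matrix.
#' @param model An [observer_model()].
#' @return A perturbed logical mask of the same dimension; never empty.
#' @export
simulate_observer <- function(mask, model) {
  assert_mask(mask)
  stopifnot(inherits(model, "observer_model"))
  if (model$boundary_jitter_sigma == 0) return(mask)

  n_angles <- 64L
  d <- with_seed_(model$seed, rnorm(n_angles, sd = model$boundary_jitter_sigma))
  # Periodic Gaussian smoothing over the circle, kernel renormalized to unit
  # l2 norm so smoothing does not shrink the displacement scale.
  step_deg <- 360 / n_angles
  lags <- seq_len(n_angles) - 1L
  ang_dist <- pmin(lags, n_angles - lags) * step_deg
  k <- dnorm(ang_dist, sd = model$smoothness)
  k <- k / sqrt(sum(k^2))
  idx <- outer(seq_len(n_angles), lags, function(i, l) ((i - 1L + l) %% n_angles) + 1L)
  d_smooth <- as.numeric(matrix(d[idx], n_angles) %*% k)

  ctr_r <- mean(which(mask, arr.ind = TRUE)[, 1])
  ctr_c <- mean(which(mask, arr.ind = TRUE)[, 2])
  nr <- nrow(mask); nc <- ncol(mask)
  r <- matrix(seq_len(nr), nr, nc) - ctr_r
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr_c
  rho <- sqrt(r^2 + c_^2)
  theta <- atan2(c_, r)  # (-pi, pi]

  # Radius of the original boundary per angular bin (star-shaped assumption).
  bin_angles <- seq(-pi, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  bin_of <- pmin(floor((theta + pi) / (2 * pi) * n_angles) + 1L, n_angles)
  r_mask <- rep(0, n_angles)
  in_bins <- bin_of[mask]
  in_rho <- rho[mask]
  agg <- tapply(in_rho, in_bins, max)
  r_mask[as.integer(names(agg))] <- agg
  # Fill angular bins the mask never reaches with the nearest populated bin.
  if (any(r_mask == 0)) {
    pop <- which(r_mask > 0)
    for (b in which(r_mask == 0)) {
      dd <- pmin(abs(pop - b), n_angles - abs(pop - b))
      r_mask[b] <- r_mask[pop[which.min(dd)]]
    }
  }

  r_new <- pmax(r_mask + d_smooth, 1)  # keep the mask non-empty
  # Linear interpolation of the displaced boundary radius over angle.
  frac <- (theta + pi) / (2 * pi) * n_angles
  i0 <- (floor(frac) %% n_angles) + 1L
  i1 <- (i0 %% n_angles) + 1L
  w <- frac - floor(frac)
  r_interp <- (1 - w) * r_new[i0] + w * r_new[i1]
  out <- rho <= r_interp
  dim(out) <- dim(mask)
  out
}

#' Generate a cohort of phantom subjects
#'
#' Draws per-subject phantom parameters uniformly from the supplied ranges and
#' generates each subject's slice and ground-truth mask. The returned tibble is
#' the cohort manifest; images and masks are carried as list-columns.
#'
#' @param n_subjects Number of subjects (>= 2; the downstream ICC is undefined
#'   for a single subject).
#' @param base_spec A [phantom_spec()] giving the shared parameters.
#' @param variation Named list of `c(min, max)` ranges sampled per subject.
#'   Recognized names: `lesion_intensity`, `background_intensity`,
#'   `lesion_rotation`, `noise_sigma`, `bias_amplitude`, `lesion_axis_a`,
#'   `lesion_axis_b`, `lesion_center_row`, `lesion_center_col`.
#' @param seed Integer seed; the cohort is a pure function of
#'   `(base_spec, variation, seed)`.
#' @return A tibble with columns `subject_id`, `image`, `mask` (list-columns),
#'   and one column per spec parameter.
#' @export
generate_cohort <- function(n_subjects, base_spec = phantom_spec(),
                            variation = list(), seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2 (ICC needs >= 2 subjects).")
  allowed <- c("lesion_intensity", "background_intensity", "lesion_rotation",
               "noise_sigma", "bias_amplitude", "lesion_axis_a", "lesion_axis_b",
               "lesion_center_row", "lesion_center_col")
  bad <- setdiff(names(variation), allowed)
  if (length(bad)) abort(paste0("unknown variation parameter(s): ",
                                paste(bad, collapse = ", ")))
  for (nm in names(variation)) {
    rg <- variation[[nm]]
    if (length(rg) != 2 || rg[1] > rg[2]) {
      abort(sprintf("variation range for `%s` must be c(min, max) with min <= max.", nm))
    }
  }
  draws <- with_seed_(derive_seed(seed, "cohort"), {
    purrr::map(seq_len(n_subjects), function(i) {
      purrr::map_dbl(variation, function(rg) runif(1, rg[1], rg[2]))
    })
  })
  rows <- purrr::map(seq_len(n_subjects), function(i) {
    v <- draws[[i]]
    sp <- base_spec
    for (nm in names(v)) {
      val <- v[[nm]]
      switch(nm,
        lesion_axis_a = { sp$lesion_axes[1] <- val },
        lesion_axis_b = { sp$lesion_axes[2] <- val },
        lesion_center_row = { sp$lesion_center[1] <- val },
        lesion_center_col = { sp$lesion_center[2] <- val },
        { sp[[nm]] <- val }
      )
    }
    sp$seed <- derive_seed(seed, "subject", i)
    sp <- validate_phantom_spec(sp)
    ph <- generate_phantom(sp)
    tibble(
      subject_id = i, image = list(ph$image), mask = list(ph$mask),
      lesion_center_row = sp$lesion_center[1], lesion_center_col = sp$lesion_center[2],
      lesion_axis_a = sp$lesion_axes[1], lesion_axis_b = sp$lesion_axes[2],
      lesion_rotation = sp$lesion_rotation,
      lesion_intensity = sp$lesion_intensity,
      background_intensity = sp$background_intensity,
      noise_sigma = sp$noise_sigma, bias_amplitude = sp$bias_amplitude,
      seed = sp$seed
    )
  })
  dplyr::bind_rows(rows)
}
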