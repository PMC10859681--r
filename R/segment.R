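#' Level-set / active-contour parameters
#'
#' Controls the geodesic active-contour evolution
#' `du/dt = g(I) (c + kappa) |grad u| (+ grad g . grad u)`,
#' where `g` is the edge indicator, `kappa` the front curvature, and `c` a
#' constant balloon speed (positive = outward). The second-order rigidity
#' weight of the parametric snake energy is fixed at zero in this pathway; the
#' elasticity and edge weights are absorbed into the curvature term and `g`.
#'
#' @param balloon Balloon speed `c`; positive grows the front, negative shrinks
#'   it. Default +0.5, suited to region-grown initializations (which tend to
#'   under-segment).
#' @param iterations Number of explicit update steps; default 100.
#' @param edge_sigma Gaussian pre-smoothing scale for the edge indicator, in
#'   pixels; default 1.5.
#' @param edge_gain Gradient gain of the edge indicator (see
#'   [edge_indicator()]); default 20, chosen so a Gaussian-smoothed edge of
#'   contrast 0.5 on a \[0, 1\] image maps to g near 0.1 and can arrest the
#'   front within the standard 100-iteration budget.
#' @param dt Time step; `NULL` (default) picks the stability bound
#'   `0.5 / (|balloon| + 4)` grid units for the explicit scheme.
#' @param reinit_every Re-initialize the level-set field to a signed distance
#'   function every this many iterations (keeps `|grad u|` near 1); default 20.
#' @param edge_advection Include the `grad g . grad u` edge-attraction term
#'   (default `TRUE`); `FALSE` runs the pure `g (c + kappa) |grad u|` flow.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(balloon = 0.5, iterations = 100, edge_sigma = 1.5,
                         edge_gain = 20, dt = NULL, reinit_every = 20,
                         edge_advection = TRUE) {
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (edge_sigma < 0) abort("`edge_sigma` must be >= 0.")
  if (edge_gain < 0) abort("`edge_gain` must be >= 0.")
  dt <- dt %||% (0.5 / (abs(balloon) + 4))
  if (dt <= 0) abort("`dt` must be > 0.")
  if (dt > 0.5 / (abs(balloon) + 4) + 1e-12) {
    warn("`dt` exceeds the stability bound 0.5 / (|balloon| + 4); the explicit scheme may oscillate.")
  }
  structure(list(balloon = balloon, iterations = as.integer(iterations),
                 edge_sigma = edge_sigma, edge_gain = edge_gain, dt = dt,
                 reinit_every = as.integer(reinit_every),
                 edge_advection = isTRUE(edge_advection)),
            class = "snake_params")
}

#' Edge-indicator field for geodesic active contours
#'
#' `g = 1 / (1 + (gain * |grad(G_sigma * I)|)^2)`: equal to 1 where the
#' smoothed image gradient vanishes and strictly decreasing in gradient
#' magnitude, so the level-set front slows down (and with the advection term is
#' pulled back) at intensity edges. `gain = 1` gives the textbook indicator
#' `1 / (1 + |grad(G_sigma * I)|^2)`.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param edge_sigma Gaussian smoothing scale in pixels (>= 0).
#' @param gain Gradient gain (>= 0); see [snake_params()] for the default used
#'   during evolution.
#' @return Matrix `g` with values in (0, 1\].
#' @export
edge_indicator <- function(image, edge_sigma = 1.5, gain = 1) {
  assert_image(image)
  if (edge_sigma < 0) abort("`edge_sigma` must be >= 0.")
  if (gain < 0) abort("`gain` must be >= 0.")
  sm <- gaussian_smooth(image, edge_sigma)
  gr <- gradient_mat(sm)
  1 / (1 + gain^2 * (gr$dr^2 + gr$dc^2))
}

#' Curvature of the level-set field
#'
#' `kappa = div(grad u / |grad u|)`, computed with central differences and the
#' regularization `|grad u| -> sqrt(|grad u|^2 + eps^2)` (`eps = 1e-8`) so flat
#' regions do not divide by zero. For a signed distance function of a circle of
#' radius `r`, `kappa = 1/r` (positive for convex fronts, mask inside `u < 0`);
#' planar fronts have `kappa = 0`.
#'
#' @param u Numeric matrix (>= 3 x 3).
#' @return Matrix of curvature values.
#' @export
curvature <- function(u) {
  if (!is.matrix(u) || nrow(u) < 3 || ncol(u) < 3) {
    abort("`u` must be a numeric matrix of at least 3 x 3.")
  }
  eps2 <- 1e-16
  ur <- (shift_mat(u, 1L, 0L) - shift_mat(u, -1L, 0L)) / 2
  uc <- (shift_mat(u, 0L, 1L) - shift_mat(u, 0L, -1L)) / 2
  urr <- shift_mat(u, 1L, 0L) - 2 * u + shift_mat(u, -1L, 0L)
  ucc <- shift_mat(u, 0L, 1L) - 2 * u + shift_mat(u, 0L, -1L)
  urc <- (shift_mat(u, 1L, 1L) - shift_mat(u, 1L, -1L) -
          shift_mat(u, -1L, 1L) + shift_mat(u, -1L, -1L)) / 4
  (urr * uc^2 - 2 * ur * uc * urc + ucc * ur^2) / (ur^2 + uc^2 + eps2)^1.5
}

# Signed Euclidean distance to the mask boundary; negative inside.
signed_distance <- function(mask) {
  fg <- matrix(as.numeric(mask), nrow(mask))
  d_in <- EBImage::distmap(fg)
  d_out <- EBImage::distmap(1 - fg)
  out <- matrix(as.numeric(d_out - d_in), nrow(mask))
  # distmap is infinite when one class is absent (all-inside / all-outside).
  cap <- nrow(mask) + ncol(mask)
  out[out > cap] <- cap
  out[out < -cap] <- -cap
  out
}

#' Evolve a geodesic active contour from an initial mask
#'
#' Runs `iterations` explicit upwind update steps of
#' `du/dt = g (c + kappa) |grad u| + grad g . grad u` starting from the signed
#' distance function of `init`, and returns the region `u < 0`. The balloon and
#' edge-advection terms use upwind (entropy-satisfying) differencing; the
#' curvature term uses central differences. `u` is re-initialized to a distance
#' function every `reinit_every` iterations.
#'
#' If the front collapses to an empty region the empty mask is returned with
#' attribute `collapsed = TRUE` and a warning (not an error).
#'
#' @param image Numeric matrix in \[0, 1\] (optionally CLAHE-enhanced).
#' @param init Non-empty logical matrix, the initial region.
#' @param params A [snake_params()].
#' @return Logical mask `u < 0` with attribute `collapsed`.
#' @export
evolve_level_set <- function(image, init, params = snake_params()) {
  assert_image(image)
  assert_mask(init, "init")
  assert_same_dim(image, init)
  stopifnot(inherits(params, "snake_params"))

  g <- edge_indicator(image, params$edge_sigma, params$edge_gain)
  gg <- gradient_mat(g)
  u <- signed_distance(init)
  c_ <- params$balloon
  dt <- params$dt

  for (it in seq_len(params$iterations)) {
    # One-sided differences for the upwind terms.
    dmr <- u - shift_mat(u, -1L, 0L); dpr <- shift_mat(u, 1L, 0L) - u
    dmc <- u - shift_mat(u, 0L, -1L); dpc <- shift_mat(u, 0L, 1L) - u

    # Balloon g*c*|grad u|: upwind gradient norm by the sign of the speed.
    speed <- g * c_
    grad_plus <- sqrt(pmax(dmr, 0)^2 + pmin(dpr, 0)^2 +
                      pmax(dmc, 0)^2 + pmin(dpc, 0)^2)
    grad_minus <- sqrt(pmin(dmr, 0)^2 + pmax(dpr, 0)^2 +
                       pmin(dmc, 0)^2 + pmax(dpc, 0)^2)
    # u < 0 inside: an outward-growing front (c > 0) makes u decrease.
    balloon_term <- -(pmax(speed, 0) * grad_plus + pmin(speed, 0) * grad_minus)

    # Curvature g*kappa*|grad u| with central differences. With u < 0 inside,
    # kappa > 0 on convex fronts and u_t = +g*kappa*|grad u| shrinks them.
    ur <- (dpr + dmr) / 2; uc <- (dpc + dmc) / 2
    grad_c <- sqrt(ur^2 + uc^2)
    curv_term <- g * curvature(u) * grad_c

    upd <- balloon_term + curv_term
    if (params$edge_advection) {
      # u_t = grad g . grad u transports level sets downhill on g (velocity
      # -grad g), so upwind takes the forward difference where grad g > 0.
      adv <- pmax(gg$dr, 0) * dpr + pmin(gg$dr, 0) * dmr +
             pmax(gg$dc, 0) * dpc + pmin(gg$dc, 0) * dmc
      upd <- upd + adv
    }
    u <- u + dt * upd
    if (params$reinit_every > 0 && it %% params$reinit_every == 0L &&
        it < params$iterations) {
      m <- u < 0
      if (!any(m)) break
      u <- signed_distance(m)
    }
  }
  out <- u < 0
  collapsed <- !any(out)
  if (collapsed) warn("level-set front collapsed to an empty region.")
  attr(out, "collapsed") <- collapsed
  out
}

#' Region growing from a seed pixel
#'
#' Returns the maximal 4-connected component containing `seed` whose
#' intensities lie within `tol` of the seed pixel's intensity.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param seed Integer length-2 `(row, col)`, 1-based, inside the image.
#' @param tol Intensity tolerance (>= 0).
#' @return Logical mask containing the seed.
#' @export
region_grow <- function(image, seed, tol) {
  assert_image(image)
  seed <- as.integer(seed)
  if (length(seed) != 2 || seed[1] < 1 || seed[1] > nrow(image) ||
      seed[2] < 1 || seed[2] > ncol(image)) {
    abort("`seed` must be a (row, col) pair inside the image.")
  }
  if (tol < 0) abort("`tol` must be >= 0.")
  candidate <- abs(image - image[seed[1], seed[2]]) <= tol
  grown <- matrix(FALSE, nrow(image), ncol(image))
  grown[seed[1], seed[2]] <- TRUE
  repeat {
    expanded <- grown |
      shift_mat(grown, 1L, 0L) | shift_mat(grown, -1L, 0L) |
      shift_mat(grown, 0L, 1L) | shift_mat(grown, 0L, -1L)
    expanded <- expanded & candidate
    if (identical(expanded, grown)) break
    grown <- expanded
  }
  grown
}

#' Load a manual lesion mask from disk
#'
#' Reads a PNG or NIfTI file and thresholds nonzero pixels to `TRUE`. When a
#' paired `image` is supplied the mask grid is validated against it.
#'
#' @param path Path to a PNG (0/255) or NIfTI (0/1) mask.
#' @param image Optional paired image matrix for shape validation.
#' @return Logical mask.
#' @export
load_manual_mask <- function(path, image = NULL) {
  m <- read_gray_image(path, normalize = FALSE)
  mask <- m > 0
  if (!any(mask)) abort(sprintf("empty mask: `%s` has no nonzero pixels.", path))
  if (!is.null(image)) assert_same_dim(image, mask)
  mask
}

#' Discrete snake (parametric contour) energy
#'
#' Evaluates the classical contour energy
#' `E = sum alpha |C'|^2 + beta |C''| - gamma sum |grad I(C)|`
#' on a closed polygonal contour: the first two terms penalize stretching and
#' bending of the curve, the third rewards placement on strong image edges.
#' This is an energy evaluator only; segmentation itself uses the level-set
#' flow of [evolve_level_set()].
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param contour Numeric matrix with columns `(row, col)`, ordered along a
#'   closed curve.
#' @param alpha,beta,gamma Non-negative elasticity, rigidity, and edge weights.
#' @return Scalar energy (lower is better).
#' @export
contour_energy <- function(image, contour, alpha = 1, beta = 0, gamma = 1) {
  assert_image(image)
  if (!is.matrix(contour) || ncol(contour) != 2 || nrow(contour) < 3) {
    abort("`contour` must be an n x 2 matrix of (row, col) points, n >= 3.")
  }
  if (alpha < 0 || beta < 0 || gamma < 0) abort("weights must be >= 0.")
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  prv <- rbind(contour[nrow(contour), , drop = FALSE], contour[-nrow(contour), , drop = FALSE])
  d1 <- nxt - contour
  d2 <- nxt - 2 * contour + prv
  internal <- alpha * sum(d1^2) + beta * sum(sqrt(rowSums(d2^2)))
  gr <- gradient_mat(image)
  gm <- sqrt(gr$dr^2 + gr$dc^2)
  ri <- pmin(pmax(round(contour[, 1]), 1L), nrow(image))
  ci <- pmin(pmax(round(contour[, 2]), 1L), ncol(image))
  external <- -gamma * sum(gm[cbind(ri, ci)])
  internal + external
}
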