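# Internal helpers shared across modules. Images are numeric matrices with
# intensities in [0, 1]; masks are logical matrices of the same dimension.

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  rng <- range(image, finite = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    abort(sprintf("`%s` intensities must lie in [0, 1]; observed [%g, %g].",
                  arg, rng[1], rng[2]))
  }
  invisible(image)
}

assert_mask <- function(mask, arg = "mask", allow_empty = FALSE) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort(sprintf("`%s` must be a logical matrix.", arg))
  }
  if (!allow_empty && !any(mask)) {
    abort(sprintf("`%s` is an empty mask.", arg))
  }
  invisible(mask)
}

assert_same_dim <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) {
    abort(sprintf(
      "image (%d x %d) and mask (%d x %d) dimensions differ.",
      nrow(image), ncol(image), nrow(mask), ncol(mask)
    ))
  }
  invisible(TRUE)
}

# Shift a matrix by (dr, dc) with replicated (clamped) borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central-difference gradient with replicated borders; returns list(dr, dc)
# in units of intensity per pixel.
gradient_mat <- function(m) {
  list(
    dr = (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2,
    dc = (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2
  )
}

# Separable Gaussian smoothing with replicated borders. sigma in pixels;
# sigma = 0 returns the input unchanged.
gaussian_smooth <- function(m, sigma) {
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (sigma == 0) return(m)
  radius <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  conv_1d <- function(x, along_rows) {
    acc <- 0
    for (i in seq_along(k)) {
      off <- i - radius - 1L
      acc <- acc + k[i] * if (along_rows) shift_mat(x, off, 0L) else shift_mat(x, 0L, off)
    }
    acc
  }
  conv_1d(conv_1d(m, TRUE), FALSE)
}

# Dilate / erode a mask with a disk structuring element of the given radius.
mask_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask)))
  mask | (d <= radius)
}

mask_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  mask & (d > radius)
}

#' Dice similarity coefficient between two masks
#'
#' `2|A∩B| / (|A| + |B|)`; equals 1 for identical non-empty masks and 0 for
#' disjoint ones. Defined as 1 when both masks are empty.
#'
#' @param a,b Logical matrices of identical dimension.
#' @return A scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  assert_mask(a, "a", allow_empty = TRUE)
  assert_mask(b, "b", allow_empty = TRUE)
  assert_same_dim(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Deterministically derive a 31-bit seed from a base seed and context labels.
derive_seed <- function(seed, ...) {
  key <- rlang::hash(list(as.integer(seed), ...))
  bits <- strtoi(substr(key, 1, 7), base = 16L)
  bits %% 2147483647L
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
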