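#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization is controlled by the clip
#' limit `CL` and the tile grid `NT`. `CL` is interpreted as a fraction of the
#' tile pixel count: each histogram bin is capped at `CL * tile_pixels` counts
#' before the tile's equalization mapping is built, which bounds how much local
#' contrast (and therefore noise) can be amplified. `CL = 1` disables clipping.
#'
#' @param clip_limit Fraction in (0, 1]; default 0.9.
#' @param n_tiles Integer length-2 `(rows, cols)` tile grid; default `c(8, 8)`.
#' @param n_bins Histogram bin count over \[0, 1\]; default 256.
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(clip_limit = 0.9, n_tiles = c(8, 8), n_bins = 256) {
  if (!is.numeric(clip_limit) || clip_limit <= 0 || clip_limit > 1) {
    abort("`clip_limit` must lie in (0, 1].")
  }
  n_tiles <- as.integer(n_tiles)
  if (length(n_tiles) != 2 || any(n_tiles < 1)) {
    abort("`n_tiles` must be two integers >= 1.")
  }
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  structure(list(clip_limit = clip_limit, n_tiles = n_tiles,
                 n_bins = as.integer(n_bins)),
            class = "clahe_params")
}

#' Clip a tile histogram and redistribute the excess
#'
#' Counts above the clip ceiling `clip_limit * sum(counts)` are removed and
#' spread uniformly over all bins in a single real-valued pass, so total mass
#' is conserved exactly and no bin exceeds `ceiling + excess / n_bins`.
#'
#' @param counts Numeric vector of per-bin counts.
#' @param clip_limit Fraction in (0, 1].
#' @return Clipped counts with the same sum as the input.
#' @examples
#' clip_histogram(c(10, 0, 0, 0), 0.4)  # ceiling 4 -> c(5.5, 1.5, 1.5, 1.5)
#' @export
clip_histogram <- function(counts, clip_limit) {
  if (!is.numeric(counts) || any(counts < 0)) {
    abort("`counts` must be non-negative numbers.")
  }
  if (clip_limit <= 0 || clip_limit > 1) abort("`clip_limit` must lie in (0, 1].")
  total <- sum(counts)
  ceiling_ <- clip_limit * total
  clipped <- pmin(counts, ceiling_)
  excess <- total - sum(clipped)
  clipped + excess / length(counts)
}

# Contiguous tile index boundaries: n items split into k runs of near-equal size.
tile_breaks <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

bin_index <- function(values, n_bins) {
  pmin(pmax(floor(values * n_bins) + 1L, 1L), n_bins)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Partitions the image into `n_tiles` contiguous tiles, equalizes each tile's
#' clipped histogram, and blends neighbouring tile mappings bilinearly (edge
#' tiles clamped), removing tile-seam artifacts. A tile whose pixels fall in a
#' single histogram bin maps intensity to itself, so constant images are fixed
#' points. Per-tile transfer functions are cumulative distributions, hence
#' non-decreasing, and output stays in \[0, 1\].
#'
#' With `clip_limit = 1` and `n_tiles = c(1, 1)` the operation degenerates to
#' plain global histogram equalization.
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param params A [clahe_params()].
#' @return Enhanced image, same dimension, intensities in \[0, 1\].
#' @export
clahe <- function(image, params = clahe_params()) {
  assert_image(image)
  stopifnot(inherits(params, "clahe_params"))
  nr <- nrow(image); nc <- ncol(image)
  tr <- params$n_tiles[1]; tc_ <- params$n_tiles[2]
  if (nr < tr || nc < tc_) {
    abort(sprintf("image (%d x %d) is smaller than the tile grid (%d x %d).",
                  nr, nc, tr, tc_))
  }
  nb <- params$n_bins
  rb <- tile_breaks(nr, tr)
  cb <- tile_breaks(nc, tc_)

  # Per-tile equalization LUT over bins; constant tiles map identically.
  n_tiles_total <- tr * tc_
  lut <- matrix(0, n_tiles_total, nb)
  constant_tile <- logical(n_tiles_total)
  bins <- bin_index(image, nb)
  for (ti in seq_len(tr)) {
    for (tj in seq_len(tc_)) {
      t_id <- (tj - 1L) * tr + ti
      b <- bins[rb[ti, 1]:rb[ti, 2], cb[tj, 1]:cb[tj, 2]]
      h <- tabulate(b, nbins = nb)
      if (sum(h > 0) <= 1L) {
        constant_tile[t_id] <- TRUE
        next
      }
      h <- clip_histogram(h, params$clip_limit)
      lut[t_id, ] <- cumsum(h) / sum(h)
    }
  }

  # Bilinear blend of the four surrounding tile mappings, clamped at edges.
  centers_r <- (rb[, 1] + rb[, 2]) / 2
  centers_c <- (cb[, 1] + cb[, 2]) / 2
  interp_axis <- function(pos, centers) {
    k <- length(centers)
    if (k == 1L) return(list(i0 = rep(1L, length(pos)), i1 = rep(1L, length(pos)),
                             w = rep(0, length(pos))))
    i0 <- pmin(pmax(findInterval(pos, centers), 1L), k - 1L)
    w <- (pos - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    list(i0 = i0, i1 = i0 + 1L, w = pmin(pmax(w, 0), 1))
  }
  ax_r <- interp_axis(seq_len(nr), centers_r)
  ax_c <- interp_axis(seq_len(nc), centers_c)

  rI0 <- matrix(ax_r$i0, nr, nc); rI1 <- matrix(ax_r$i1, nr, nc)
  rW <- matrix(ax_r$w, nr, nc)
  cI0 <- matrix(ax_c$i0, nr, nc, byrow = TRUE); cI1 <- matrix(ax_c$i1, nr, nc, byrow = TRUE)
  cW <- matrix(ax_c$w, nr, nc, byrow = TRUE)

  tile_value <- function(ti, tj) {
    t_id <- as.vector((tj - 1L) * tr + ti)
    v <- lut[cbind(t_id, as.vector(bins))]
    const <- constant_tile[t_id]
    v[const] <- as.vector(image)[const]
    v
  }
  # Blend as image + sum(w_i * (m_i(v) - v)) so identity tile mappings (and
  # hence constant images) are exact fixed points.
  v0 <- as.vector(image)
  out <- v0 +
    as.vector((1 - rW) * (1 - cW)) * (tile_value(rI0, cI0) - v0) +
    as.vector((1 - rW) * cW)       * (tile_value(rI0, cI1) - v0) +
    as.vector(rW * (1 - cW))       * (tile_value(rI1, cI0) - v0) +
    as.vector(rW * cW)             * (tile_value(rI1, cI1) - v0)
  matrix(pmin(pmax(out, 0), 1), nr, nc)
}
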