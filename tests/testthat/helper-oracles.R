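# Independent oracle implementations used to cross-check the package.
# Deliberately written in the most literal (loop-based) style: these must not
# share code paths with the implementations they verify.

mk_disk <- function(n, r0, ctr = (n + 1) / 2) {
  x <- matrix(seq_len(n), n, n) - ctr
  sqrt(x^2 + t(x)^2) <= r0
}

# --- GLCM -------------------------------------------------------------------

# Exhaustive pair enumeration over all pixel pairs at one offset.
oracle_glcm <- function(q, mask, dr, dc, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (mask[r, cc] && r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
          mask[r2, c2]) {
        a <- q[r, cc] + 1L; b <- q[r2, c2] + 1L
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

# Textbook Haralick-family formulas, scalar accumulation.
oracle_glcm_features <- function(P) {
  N <- nrow(P)
  lg2 <- function(p) if (p > 0) log2(p) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:N) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sdx <- 0; sdy <- 0
  for (i in 1:N) { sdx <- sdx + (i - mux)^2 * px[i]; sdy <- sdy + (i - muy)^2 * py[i] }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)

  auto <- 0; contr <- 0; diss <- 0; ener <- 0; entr <- 0; h1 <- 0; h2 <- 0
  cs <- 0; cp <- 0; ssq <- 0; idn <- 0; idmn <- 0
  mu <- 0
  for (i in 1:N) for (j in 1:N) mu <- mu + i * P[i, j]
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    auto <- auto + i * j * p
    contr <- contr + (i - j)^2 * p
    diss <- diss + abs(i - j) * p
    ener <- ener + p^2
    entr <- entr - p * lg2(p)
    h1 <- h1 + p / (1 + abs(i - j))
    h2 <- h2 + p / (1 + (i - j)^2)
    cs <- cs + (i + j - mux - muy)^3 * p
    cp <- cp + (i + j - mux - muy)^4 * p
    ssq <- ssq + (i - mu)^2 * p
    idn <- idn + p / (1 + abs(i - j) / N)
    idmn <- idmn + p / (1 + (i - j)^2 / N^2)
  }
  corr <- if (sdx > 0 && sdy > 0) (auto - mux * muy) / (sdx * sdy) else 0

  psum <- rep(0, 2 * N); pdiff <- rep(0, N)  # indices k and k+1 (k = 0..N-1)
  for (i in 1:N) for (j in 1:N) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (k in 2:(2 * N)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * N)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * N)) se <- se - psum[k] * lg2(psum[k])
  mud <- 0; for (k in 0:(N - 1)) mud <- mud + k * pdiff[k + 1]
  dv <- 0; for (k in 0:(N - 1)) dv <- dv + (k - mud)^2 * pdiff[k + 1]
  de <- 0; for (k in 0:(N - 1)) de <- de - pdiff[k + 1] * lg2(pdiff[k + 1])

  hx <- 0; for (i in 1:N) hx <- hx - px[i] * lg2(px[i])
  hy <- 0; for (j in 1:N) hy <- hy - py[j] * lg2(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:N) for (j in 1:N) {
    hxy1 <- hxy1 - P[i, j] * lg2(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg2(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (entr - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - entr)), 0))

  c(glcm_autocorrelation = auto, glcm_contrast = contr, glcm_correlation = corr,
    glcm_cluster_prominence = cp, glcm_cluster_shade = cs,
    glcm_dissimilarity = diss, glcm_energy = ener, glcm_entropy = entr,
    glcm_homogeneity1 = h1, glcm_homogeneity2 = h2,
    glcm_maximum_probability = max(P), glcm_sum_of_squares = ssq,
    glcm_sum_average = sa, glcm_sum_variance = sv, glcm_sum_entropy = se,
    glcm_difference_variance = dv, glcm_difference_entropy = de,
    glcm_imc1 = imc1, glcm_imc2 = imc2, glcm_idn = idn, glcm_idmn = idmn)
}

random_glcm <- function(n = 8) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  m / sum(m)
}

# --- ICC --------------------------------------------------------------------

# Sums-of-squares decomposition by explicit loops, then moment-based variance
# components (rater component truncated at zero).
oracle_icc <- function(m, model) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  rm <- numeric(n); cm <- numeric(k)
  for (i in 1:n) rm[i] <- sum(m[i, ]) / k
  for (j in 1:k) cm[j] <- sum(m[, j]) / n
  ssr <- 0; for (i in 1:n) ssr <- ssr + k * (rm[i] - grand)^2
  ssc <- 0; for (j in 1:k) ssc <- ssc + n * (cm[j] - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - rm[i] - cm[j] + grand)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 && msc == 0 && mse == 0) return(1)
  var_r <- max((msr - mse) / k, 0)
  var_c <- max((msc - mse) / n, 0)
  var_e <- mse
  if (model == "agreement") var_r / (var_r + var_c + var_e)
  else var_r / (var_r + var_e)
}

oracle_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  rm <- rowSums(m) / k; cm <- colSums(m) / n
  ssr <- 0; for (i in 1:n) ssr <- ssr + k * (rm[i] - grand)^2
  ssc <- 0; for (j in 1:k) ssc <- ssc + n * (cm[j] - grand)^2
  sse <- 0; ssw <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - rm[i] - cm[j] + grand)^2
    ssw <- ssw + (m[i, j] - rm[i])^2
  }
  list(ms_rows = ssr / (n - 1), ms_cols = ssc / (k - 1),
       ms_error = sse / ((n - 1) * (k - 1)), ms_within = ssw / (n * (k - 1)))
}

# --- CLAHE / histogram equalization ----------------------------------------

# Brute-force global histogram equalization: v -> cdf(bin(v)).
oracle_hist_equalize <- function(image, n_bins = 256) {
  bins <- pmin(pmax(floor(image * n_bins) + 1L, 1L), n_bins)
  h <- tabulate(bins, nbins = n_bins)
  cdf <- cumsum(h) / sum(h)
  matrix(cdf[bins], nrow(image), ncol(image))
}

# --- edge indicator ---------------------------------------------------------

# Naive 2-D Gaussian convolution (replicated borders) + central differences.
oracle_edge_indicator <- function(image, sigma, gain = 1) {
  nr <- nrow(image); nc <- ncol(image)
  radius <- max(1L, ceiling(3 * sigma))
  k1 <- dnorm(seq(-radius, radius), sd = sigma); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  sm <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (i in -radius:radius) for (j in -radius:radius) {
      ri <- min(max(r + i, 1L), nr); ci <- min(max(cc + j, 1L), nc)
      acc <- acc + k2[i + radius + 1, j + radius + 1] * image[ri, ci]
    }
    sm[r, cc] <- acc
  }
  gr2 <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    rp <- min(r + 1L, nr); rm <- max(r - 1L, 1L)
    cp <- min(cc + 1L, nc); cm <- max(cc - 1L, 1L)
    dr <- (sm[rp, cc] - sm[rm, cc]) / 2
    dc <- (sm[r, cp] - sm[r, cm]) / 2
    gr2[r, cc] <- dr^2 + dc^2
  }
  1 / (1 + gain^2 * gr2)
}

# --- NIfTI fixture ----------------------------------------------------------

# Minimal single-slice float32 NIfTI-1 writer with raw (unscaled) data and an
# explicit scl_slope / scl_inter header, so reader conformance can be checked.
write_nifti1_raw <- function(data, path, slope = 1, inter = 0) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(c(2L, nrow(data), ncol(data), 1L, 1L, 1L, 1L, 1L)),
           con, size = 2)
  writeBin(raw(14), con)
  writeBin(16L, con, size = 2)   # datatype: float32
  writeBin(32L, con, size = 2)   # bitpix
  writeBin(0L, con, size = 2)
  writeBin(rep(1, 8), con, size = 4)  # pixdim
  writeBin(352, con, size = 4)   # vox_offset
  writeBin(slope, con, size = 4)
  writeBin(inter, con, size = 4)
  writeBin(raw(224), con)
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(5), con)
  writeBin(as.numeric(data), con, size = 4)  # column-major, matching R
  invisible(path)
}

# Random lesion geometry for segmentation-recovery suites.
random_phantom_geometry <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- runif(1, 10, 24)
      list(a = a, b = runif(1, 8, a), rot = runif(1, 0, 180),
           ctr = 48 + runif(2, -8, 8))
    })
  })
}
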