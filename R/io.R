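#' Read a 2-D grayscale image
#'
#' Supports 8/16-bit grayscale PNG and NIfTI (`.nii` / `.nii.gz`). PNG values
#' arrive already scaled by bit depth to \[0, 1\]. NIfTI voxels have the stored
#' `scl_slope` / `scl_inter` applied (`slope * v + inter`); when
#' `normalize = TRUE`, values already inside \[0, 1\] are kept as-is (so float
#' round trips are lossless) and anything else is linearly rescaled by its
#' data range to \[0, 1\]. Color or multi-frame inputs are rejected.
#'
#' @param path Path to a `.png`, `.nii`, or `.nii.gz` file.
#' @param normalize Rescale to \[0, 1\] (default `TRUE`). With `FALSE` the
#'   slope/intercept-corrected raw values are returned (used for mask files).
#' @return Numeric matrix (rows x cols).
#' @export
read_gray_image <- function(path, normalize = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: `%s`.", path))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", path))
  if (ext == ".png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] == 2) {
        img <- img[, , 1]  # gray + alpha
      } else {
        abort(sprintf("unsupported format: `%s` is a color PNG; grayscale required.", path))
      }
    }
    if (!normalize) img <- img * 255
    return(unclass(img))
  }
  if (ext %in% c(".nii", ".nii.gz")) {
    nii <- RNifti::readNifti(path)  # RNifti applies scl_slope/scl_inter
    arr <- as.array(nii)
    d <- dim(arr)
    if (length(d) > 2) {
      if (prod(d[-(1:2)]) != 1) {
        abort(sprintf("unsupported format: `%s` has %d frames; single-slice required.",
                      path, prod(d[-(1:2)])))
      }
      arr <- array(arr, dim = d[1:2])
    }
    arr <- matrix(as.numeric(arr), d[1], d[2])
    if (normalize) {
      rng <- range(arr)
      if (rng[1] < 0 || rng[2] > 1) {
        arr <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
      }
    }
    return(arr)
  }
  abort(sprintf("unsupported format `%s`: use .png, .nii, or .nii.gz.", ext))
}

#' Write a 2-D grayscale image
#'
#' PNG output is written at 16-bit depth (quantization error at most 1/65535);
#' NIfTI output stores the floating-point values directly. Logical masks are
#' written as 0/255 PNG or 0/1 NIfTI.
#'
#' @param image Numeric matrix in \[0, 1\] or logical mask matrix.
#' @param path Destination ending in `.png`, `.nii`, or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  is_mask <- is.logical(image)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z0-9]+)$", "\\1", path))
  if (ext == ".png") {
    if (is_mask) {
      png::writePNG(matrix(as.numeric(image), nrow(image)), path)  # 0/255, 8-bit
    } else {
      assert_image(image)
      write_png16(image, path)
    }
  } else if (ext %in% c(".nii", ".nii.gz")) {
    m <- if (is_mask) matrix(as.numeric(image), nrow(image)) else image
    RNifti::writeNifti(RNifti::asNifti(array(m, dim = c(dim(m), 1))), path)
  } else {
    abort(sprintf("unsupported format `%s`: use .png, .nii, or .nii.gz.", ext))
  }
  invisible(path)
}

#' Write a cohort manifest and its images to disk
#'
#' Writes each subject's image and ground-truth mask as PNG (16-bit image,
#' 0/255 mask) plus a CSV manifest of file paths and phantom parameters.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort |>
    dplyr::mutate(
      image_path = file.path(dir, sprintf("subject%03d_image.png", .data$subject_id)),
      mask_path = file.path(dir, sprintf("subject%03d_mask.png", .data$subject_id))
    )
  purrr::pwalk(list(manifest$image, manifest$mask,
                    manifest$image_path, manifest$mask_path),
               function(im, mk, ip, mp) {
                 write_gray_image(im, ip)
                 write_gray_image(mk, mp)
               })
  out <- dplyr::select(manifest, -"image", -"mask")
  csv <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(out, csv, row.names = FALSE)
  invisible(csv)
}

# --- minimal 16-bit grayscale PNG writer -------------------------------------
# The installed PNG bindings read 16-bit files but only write 8-bit, so the
# 16-bit encoder (PNG container + zlib stream + CRC32) lives here.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c_ <- n
    for (i in 1:8) {
      c_ <- if (bitwAnd(c_, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c_, 1L))  # 0xEDB88320
      } else {
        bitwShiftR(c_, 1L)
      }
    }
    tab[n + 1] <- c_
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (x in b) {
    idx <- bitwAnd(bitwXor(crc, x), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

uint32_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(uint32_be(length(data)), body, uint32_be(crc %% 4294967296))
}

write_png16 <- function(image, path) {
  nr <- nrow(image); nc <- ncol(image)
  v <- as.integer(round(pmin(pmax(image, 0), 1) * 65535))
  # scanlines are rows of the displayed image; big-endian samples, filter 0
  hi <- v %/% 256L; lo <- v %% 256L
  scan <- matrix(raw(1), nrow = 2L * nc + 1L, ncol = nr)
  scan[seq(2L, 2L * nc, by = 2L), ] <- as.raw(t(matrix(hi, nr, nc)))
  scan[seq(3L, 2L * nc + 1L, by = 2L), ] <- as.raw(t(matrix(lo, nr, nc)))
  idat <- memCompress(as.vector(scan), type = "gzip")
  ihdr <- c(uint32_be(nc), uint32_be(nr), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
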