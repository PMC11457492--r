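## Shared containers, coordinate conventions and small numeric helpers.
##
## Conventions used throughout the package:
##   * physical coordinates are nanometres, origin at the image/volume corner,
##     x to the right, y down, z from the apical surface into the cell;
##   * pixel/voxel (1,1[,1]) covers the half-open box [0, size_nm) on each
##     axis, so the centre of pixel [r, c] sits at ((c - 0.5) px, (r - 0.5) px);
##   * image matrices are indexed [row = y, col = x]; volumes [x, y, z].

#' Calibrated 2D image
#'
#' A minimal container for a grayscale image with physical calibration,
#' produced by [render_cross_section()] and consumed by the packing and
#' Fourier modules.
#'
#' @param pixels Numeric matrix, rows indexing y (down), columns x (right).
#' @param pixel_size_nm Positive scalar, edge length of one pixel in nm.
#' @return An object of class `tm_image` with elements `pixels` and
#'   `pixel_size_nm`.
#' @export
tm_image <- function(pixels, pixel_size_nm) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (!all(is.finite(pixels))) abort("`pixels` must be finite.")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("`pixel_size_nm` must be a positive scalar.")
  }
  structure(list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "tm_image")
}

#' @export
print.tm_image <- function(x, ...) {
  cat(sprintf("<tm_image> %d x %d px, %.3g nm/px (%.3g x %.3g nm)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              ncol(x$pixels) * x$pixel_size_nm,
              nrow(x$pixels) * x$pixel_size_nm))
  invisible(x)
}

#' Calibrated 3D binary volume
#'
#' Container for one segmented channel of a 3D stack. The z axis is the
#' apicobasal axis with z = 0 at the apical surface.
#'
#' @param voxels Logical (or 0/1 numeric) 3D array indexed `[x, y, z]`.
#' @param voxel_size_nm Numeric length-3 vector `(x, y, z)` voxel pitch in nm.
#' @param channel One of `"actin"`, `"microtubule"`, `"cell"`,
#'   `"bundle_region"`.
#' @return An object of class `tm_volume`.
#' @export
tm_volume <- function(voxels, voxel_size_nm,
                      channel = c("actin", "microtubule", "cell",
                                  "bundle_region")) {
  channel <- match.arg(channel)
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array.")
  }
  if (is.numeric(voxels)) voxels <- array(voxels != 0, dim = dim(voxels))
  if (!is.logical(voxels)) abort("`voxels` must be logical or 0/1 numeric.")
  if (length(voxel_size_nm) != 3 || any(!is.finite(voxel_size_nm)) ||
      any(voxel_size_nm <= 0)) {
    abort("`voxel_size_nm` must be three positive numbers (x, y, z).")
  }
  structure(list(voxels = voxels, voxel_size_nm = as.numeric(voxel_size_nm),
                 channel = channel),
            class = "tm_volume")
}

#' @export
print.tm_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tm_volume> %s, %d x %d x %d vox @ (%g, %g, %g) nm, %d on\n",
              x$channel, d[1], d[2], d[3], x$voxel_size_nm[1],
              x$voxel_size_nm[2], x$voxel_size_nm[3], sum(x$voxels)))
  invisible(x)
}

## --- coordinate helpers ----------------------------------------------------

# nm coordinate -> 1-based pixel index (half-open pixels)
nm_to_index <- function(coord_nm, pixel_size_nm) {
  floor(coord_nm / pixel_size_nm) + 1L
}

# centre of a 1-based pixel index, in nm
index_to_nm <- function(idx, pixel_size_nm) {
  (idx - 0.5) * pixel_size_nm
}

## --- FFT helpers -----------------------------------------------------------

# Move DC to position floor(n/2)+1 on each axis (and back with inverse = TRUE).
fftshift2 <- function(m, inverse = FALSE) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  if (inverse) { s1 <- n1 - s1; s2 <- n2 - s2 }
  m[c(seq_len(n1 - s1) + s1, seq_len(s1)),
    c(seq_len(n2 - s2) + s2, seq_len(s2)), drop = FALSE]
}

# Centered frequency (cycles per nm) of each bin along an axis of length n.
freq_axis <- function(n, pixel_size_nm) {
  (seq_len(n) - (floor(n / 2) + 1)) / (n * pixel_size_nm)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

## --- interpolation ---------------------------------------------------------

# Bilinear interpolation of img at continuous pixel coordinates (x, y), where
# the centre of pixel [r, c] is at (c - 0.5, r - 0.5). Out-of-bounds -> NA.
interp_bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- x - 0.5; cy <- y - 0.5          # coordinates in pixel-centre units
  c0 <- floor(cx); r0 <- floor(cy)
  fx <- cx - c0; fy <- cy - r0
  c0 <- c0 + 1L; r0 <- r0 + 1L          # 1-based index of lower neighbour
  out <- rep(NA_real_, length(x))
  ok <- c0 >= 1L & c0 + 1L <= nc & r0 >= 1L & r0 + 1L <= nr
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1L)
    i10 <- cbind(r0[ok] + 1L, c0[ok]); i11 <- cbind(r0[ok] + 1L, c0[ok] + 1L)
    out[ok] <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      img[i01] * fx[ok] * (1 - fy[ok]) +
      img[i10] * (1 - fx[ok]) * fy[ok] +
      img[i11] * fx[ok] * fy[ok]
  }
  out
}

## --- misc ------------------------------------------------------------------

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar.", name))
  }
  invisible(x)
}

assert_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a nonnegative finite scalar.", name))
  }
  invisible(x)
}

# Midpoint-convention median (stats::median already averages the two central
# order statistics for even n; wrapped for a single documented entry point).
median_mid <- function(x) stats::median(x)
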