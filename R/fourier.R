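## Fourier-space lattice analysis: power spectra, reflection detection,
## circular/hexagonal masking with inverse transform, and back-mapping of
## ordered filaments.

#' Centered power spectrum of a calibrated image
#'
#' The image mean is subtracted and a separable Hann window applied before
#' the FFT to suppress edge streaks; the squared modulus is returned with
#' the zero frequency centered.
#'
#' @param image A [tm_image()] at least 16 px on each side.
#' @return An object of class `tm_spectrum`: list with `power` (matrix,
#'   DC at `floor(n/2)+1`), `freq_row_step`, `freq_col_step` (cycles per nm
#'   per bin on each axis) and `pixel_size_nm`.
#' @export
power_spectrum <- function(image) {
  stopifnot(inherits(image, "tm_image"))
  px <- image$pixel_size_nm
  m <- image$pixels
  if (nrow(m) < 16 || ncol(m) < 16) abort("image must be at least 16 px.")
  w <- outer(hann_window(nrow(m)), hann_window(ncol(m)))
  f <- fft((m - mean(m)) * w)
  pw <- fftshift2(Mod(f)^2)
  structure(list(power = pw,
                 freq_row_step = 1 / (nrow(m) * px),
                 freq_col_step = 1 / (ncol(m) * px),
                 pixel_size_nm = px),
            class = "tm_spectrum")
}

# centered frequency coordinate matrices (cycles/nm) of a spectrum-sized grid
spectrum_freq_grid <- function(nr, nc, fr, fc) {
  fy <- freq_axis_steps(nr) * fr
  fx <- freq_axis_steps(nc) * fc
  list(fy = matrix(fy, nr, nc), fx = matrix(fx, nr, nc, byrow = TRUE))
}

freq_axis_steps <- function(n) seq_len(n) - (floor(n / 2) + 1)

#' Detect predominant lattice reflections in a power spectrum
#'
#' Searches the annulus corresponding to a real-space spacing range for
#' local maxima exceeding `peak_factor` times the annulus median power,
#' suppresses non-maximal peaks within an angular window, and enforces
#' centrosymmetric pairing (the spectrum of a real image is point
#' symmetric). The ring radius is the magnitude-weighted mean radius of the
#' accepted peaks.
#'
#' @param spec A `tm_spectrum` from [power_spectrum()].
#' @param spacing_range_nm Real-space spacing interval `(d_min, d_max)` nm;
#'   the annulus is `[1/d_max, 1/d_min]` cycles/nm and must sit inside the
#'   Nyquist disc.
#' @param peak_factor Acceptance threshold as a multiple of the annulus
#'   median power. Point-process speckle is exponential-tailed, so the
#'   maximum over a few thousand annulus bins reaches 10-25x the median in
#'   featureless images; true lattice reflections sit orders of magnitude
#'   higher. The default of 50 rejects speckle while accepting any real
#'   reflection.
#' @param rel_magnitude Peaks weaker than this fraction of the strongest
#'   accepted peak are dropped; "predominant reflections" needs an explicit
#'   dominance criterion.
#' @param angular_window_deg Angular non-maximum-suppression window.
#' @return An object of class `tm_reflections`: tibble with `row`, `col`
#'   (bin indices), `fx`, `fy` (cycles/nm), `radius_nm_inv`, `angle_deg`,
#'   `magnitude`; attribute `ring_radius_nm_inv`. Zero rows (with a message)
#'   when no peak clears the background.
#' @export
detect_reflections <- function(spec, spacing_range_nm = c(7, 12),
                               peak_factor = 50, rel_magnitude = 0.05,
                               angular_window_deg = 15) {
  stopifnot(inherits(spec, "tm_spectrum"))
  if (length(spacing_range_nm) != 2 || any(spacing_range_nm <= 0) ||
      diff(spacing_range_nm) <= 0) {
    abort("`spacing_range_nm` must be an increasing positive interval.")
  }
  r_lo <- 1 / spacing_range_nm[2]
  r_hi <- 1 / spacing_range_nm[1]
  nyq <- 1 / (2 * spec$pixel_size_nm)
  if (r_hi > nyq) abort("spacing range maps outside the Nyquist disc.")
  pw <- spec$power
  nr <- nrow(pw); nc <- ncol(pw)
  g <- spectrum_freq_grid(nr, nc, spec$freq_row_step, spec$freq_col_step)
  rad <- sqrt(g$fx^2 + g$fy^2)
  annulus <- rad >= r_lo & rad <= r_hi
  bg <- median(pw[annulus])

  empty <- function(msg) {
    message(msg)
    out <- tibble(row = integer(0), col = integer(0), fx = numeric(0),
                  fy = numeric(0), radius_nm_inv = numeric(0),
                  angle_deg = numeric(0), magnitude = numeric(0))
    attr(out, "ring_radius_nm_inv") <- NA_real_
    class(out) <- c("tm_reflections", class(out))
    return(out)
  }

  core <- pw[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= pw[1:(nr - 2), 2:(nc - 1)] & core >= pw[3:nr, 2:(nc - 1)] &
    core >= pw[2:(nr - 1), 1:(nc - 2)] & core >= pw[2:(nr - 1), 3:nc] &
    core >= pw[1:(nr - 2), 1:(nc - 2)] & core >= pw[1:(nr - 2), 3:nc] &
    core >= pw[3:nr, 1:(nc - 2)] & core >= pw[3:nr, 3:nc]
  cand <- which(is_max, arr.ind = TRUE) + 1L
  cand <- cand[annulus[cand], , drop = FALSE]
  if (nrow(cand) == 0) return(empty("no local maxima in the annulus"))
  mag <- pw[cand]
  keep <- mag > peak_factor * bg & mag >= rel_magnitude * max(mag)
  cand <- cand[keep, , drop = FALSE]; mag <- mag[keep]
  if (nrow(cand) == 0) {
    return(empty(sprintf(
      "no reflection exceeds %g x the annulus median power", peak_factor)))
  }

  ang <- atan2(g$fy[cand], g$fx[cand]) * 180 / pi
  ord <- order(mag, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; mag <- mag[ord]; ang <- ang[ord]
  acc <- integer(0)
  for (k in seq_along(mag)) {
    if (length(acc)) {
      da <- abs(ang[k] - ang[acc])
      da <- pmin(da, 360 - da)
      if (any(da < angular_window_deg)) next
    }
    acc <- c(acc, k)
  }
  cand <- cand[acc, , drop = FALSE]; mag <- mag[acc]

  # centrosymmetric completion: add the mirror of any unpaired peak
  ctr <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)
  mir <- cbind(2L * ctr[1] - cand[, 1], 2L * ctr[2] - cand[, 2])
  have <- paste(cand[, 1], cand[, 2])
  add <- !(paste(mir[, 1], mir[, 2]) %in% have) &
    mir[, 1] >= 1 & mir[, 1] <= nr & mir[, 2] >= 1 & mir[, 2] <= nc
  if (any(add)) {
    cand <- rbind(cand, mir[add, , drop = FALSE])
    mag <- c(mag, pw[mir[add, , drop = FALSE]])
  }

  out <- tibble(row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
                fx = g$fx[cand], fy = g$fy[cand],
                radius_nm_inv = rad[cand],
                angle_deg = atan2(g$fy[cand], g$fx[cand]) * 180 / pi,
                magnitude = mag) |>
    dplyr::arrange(dplyr::desc(.data$magnitude))
  attr(out, "ring_radius_nm_inv") <-
    sum(out$radius_nm_inv * out$magnitude) / sum(out$magnitude)
  class(out) <- c("tm_reflections", class(out))
  out
}

#' Fourier-mask an image over its lattice reflections and back-map filaments
#'
#' Applies a circular (equidistant packing) or hexagonal (six-disc) mask
#' over the predominant reflections in frequency space, inverse transforms,
#' and thresholds the filtered image at a quantile of its positive values to
#' produce the highlighted-filament mask. The frequency mask is point
#' symmetric so the inverse transform is real.
#'
#' @param image A [tm_image()] (same image the spectrum was computed from).
#' @param refl A `tm_reflections` from [detect_reflections()]. Circular mode
#'   only needs its ring radius; hexagonal mode requires exactly six usable
#'   peaks.
#' @param mode `"circular"` or `"hexagonal"`.
#' @param polarity Filament polarity of the input image; dark filaments are
#'   sign-flipped internally so the filtered image peaks at filament sites.
#' @param ring_halfwidth_frac Annulus half-width as a fraction of the ring
#'   radius (circular mode).
#' @param disc_radius_frac Mask-disc radius as a fraction of the ring radius
#'   (hexagonal mode); "as tight as possible" around each reflection.
#' @param threshold_quantile Quantile of the positive filtered values used
#'   to binarise the back-mapped image.
#' @return An object of class `tm_latfilter`: list with `mode`, `filtered`
#'   ([tm_image()]), `freq_mask`, `highlighted_mask` (logical matrices) and
#'   `threshold`.
#' @export
lattice_filter <- function(image, refl, mode = c("circular", "hexagonal"),
                           polarity = c("dark_filaments", "bright_filaments"),
                           ring_halfwidth_frac = 0.10,
                           disc_radius_frac = 0.15,
                           threshold_quantile = 0.70) {
  stopifnot(inherits(image, "tm_image"))
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  ring <- attr(refl, "ring_radius_nm_inv")
  if (!isTRUE(is.finite(ring))) {
    abort("reflection set has no usable ring radius")
  }
  m <- image$pixels
  nr <- nrow(m); nc <- ncol(m)
  px <- image$pixel_size_nm
  g <- spectrum_freq_grid(nr, nc, 1 / (nr * px), 1 / (nc * px))
  rad <- sqrt(g$fx^2 + g$fy^2)
  if (mode == "circular") {
    mask <- abs(rad - ring) <= ring_halfwidth_frac * ring
  } else {
    if (nrow(refl) != 6) {
      abort(sprintf(
        "hexagonal mode needs exactly 6 usable reflections, got %d",
        nrow(refl)))
    }
    mask <- matrix(FALSE, nr, nc)
    rr <- disc_radius_frac * ring
    for (k in seq_len(6)) {
      mask <- mask |
        (g$fx - refl$fx[k])^2 + (g$fy - refl$fy[k])^2 <= rr^2
    }
    # enforce point symmetry about the DC bin (guards uneven peak sets)
    ctr <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)
    onpx <- which(mask, arr.ind = TRUE)
    mir <- cbind(2L * ctr[1] - onpx[, 1], 2L * ctr[2] - onpx[, 2])
    ok <- mir[, 1] >= 1 & mir[, 1] <= nr & mir[, 2] >= 1 & mir[, 2] <= nc
    mask[mir[ok, , drop = FALSE]] <- TRUE
  }
  s <- if (polarity == "dark_filaments") -m else m
  f <- fftshift2(fft(s - mean(s)))
  filtered <- Re(fft(fftshift2(f * mask, inverse = TRUE), inverse = TRUE)) /
    (nr * nc)
  pos <- filtered[filtered > 0]
  if (length(pos) == 0) {
    thr <- Inf
  } else {
    thr <- quantile(pos, threshold_quantile, names = FALSE)
  }
  structure(list(mode = mode,
                 filtered = tm_image(filtered, px),
                 freq_mask = mask,
                 highlighted_mask = filtered >= thr & is.finite(thr),
                 threshold = thr),
            class = "tm_latfilter")
}

#' Fraction of filament centres highlighted by a lattice filter
#'
#' The per-bundle statistic used to quantify uniform spacing: the fraction
#' of points whose pixel (or any pixel within `tol_nm`) is on in the
#' highlighted mask. Vacancy sites are naturally excluded because only
#' existing points are evaluated.
#'
#' @param result A `tm_latfilter` from [lattice_filter()].
#' @param points Tibble with `x_nm`, `y_nm` sharing the image calibration.
#' @param tol_nm Search radius around each point; 0 checks only the nearest
#'   pixel.
#' @return A single number in `[0, 1]`.
#' @export
highlighted_fraction <- function(result, points, tol_nm = 0) {
  stopifnot(inherits(result, "tm_latfilter"))
  if (nrow(points) == 0) abort("empty point set")
  mask <- result$highlighted_mask
  px <- result$filtered$pixel_size_nm
  nr <- nrow(mask); nc <- ncol(mask)
  w <- ceiling(tol_nm / px)
  hit <- vapply(seq_len(nrow(points)), function(k) {
    ci <- nm_to_index(points$x_nm[k], px)
    ri <- nm_to_index(points$y_nm[k], px)
    rs <- max(1L, ri - w):min(nr, ri + w)
    cs <- max(1L, ci - w):min(nc, ci + w)
    if (ri < 1 || ri > nr || ci < 1 || ci > nc) return(FALSE)
    if (w == 0) return(mask[ri, ci])
    sub <- mask[rs, cs, drop = FALSE]
    if (!any(sub)) return(FALSE)
    on <- which(sub, arr.ind = TRUE)
    dx <- (cs[on[, 2]] - 0.5) * px - points$x_nm[k]
    dy <- (rs[on[, 1]] - 0.5) * px - points$y_nm[k]
    any(dx^2 + dy^2 <= tol_nm^2 + (px / 2)^2)
  }, logical(1))
  mean(hit)
}
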