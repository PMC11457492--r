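#' Rendering parameters for synthetic EM-like cross-sections
#'
#' @param pixel_size_nm Pixel edge in nm. Must satisfy
#'   `pixel_size_nm <= spacing/2` of any lattice it renders.
#' @param psf_sigma_nm SD of the Gaussian blob drawn for each filament, nm.
#' @param noise_sd Additive Gaussian noise SD, in intensity units of the
#'   `[0, 1]` image range.
#' @param polarity `"dark_filaments"` (TEM-like, default) or
#'   `"bright_filaments"`.
#' @param image_shape_px Length-2 integer `(rows, cols)`.
#' @param background_level Background intensity in `[0, 1]`.
#' @param contrast Peak blob amplitude subtracted from (dark) or added to
#'   (bright) the background.
#' @param seed Integer seed for the noise field.
#' @return A list of class `render_spec`.
#' @export
render_spec <- function(pixel_size_nm = 1,
                        psf_sigma_nm = 2.5,
                        noise_sd = 0,
                        polarity = c("dark_filaments", "bright_filaments"),
                        image_shape_px = c(128L, 128L),
                        background_level = 0.8,
                        contrast = 0.5,
                        seed = 1L) {
  polarity <- match.arg(polarity)
  assert_scalar_pos(pixel_size_nm, "pixel_size_nm")
  assert_scalar_nonneg(psf_sigma_nm, "psf_sigma_nm")
  assert_scalar_nonneg(noise_sd, "noise_sd")
  if (length(image_shape_px) != 2 || any(image_shape_px < 1)) {
    abort("`image_shape_px` must be two positive integers.")
  }
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 noise_sd = noise_sd, polarity = polarity,
                 image_shape_px = as.integer(image_shape_px),
                 background_level = background_level, contrast = contrast,
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Render filament centres as an EM-like cross-section image
#'
#' Each filament is drawn as an isotropic Gaussian blob of SD
#' `psf_sigma_nm` centred at its coordinate; blobs are summed, subtracted
#' from (dark polarity) or added to (bright) the background, Gaussian noise
#' is added, and the image is clipped to `[0, 1]`.
#'
#' @param points Tibble with `x_nm`, `y_nm` columns (e.g. from
#'   [gen_lattice_points()]).
#' @param render A [render_spec()].
#' @return A [tm_image()] with `pixel_size_nm = render$pixel_size_nm`.
#' @export
render_cross_section <- function(points, render) {
  stopifnot(inherits(render, "render_spec"))
  nr <- render$image_shape_px[1]; nc <- render$image_shape_px[2]
  px <- render$pixel_size_nm
  w_nm <- nc * px; h_nm <- nr * px
  if (nrow(points) > 0) {
    bad <- points$x_nm < 0 | points$x_nm >= w_nm |
      points$y_nm < 0 | points$y_nm >= h_nm
    if (any(bad)) {
      abort(sprintf(
        "%d point(s) outside the %g x %g nm field of view (ids: %s).",
        sum(bad), w_nm, h_nm,
        paste(utils::head(points$id[bad] %||% which(bad), 10),
              collapse = ", ")))
    }
  }
  blobs <- matrix(0, nr, nc)
  if (nrow(points) > 0 && render$psf_sigma_nm > 0) {
    xc <- index_to_nm(seq_len(nc), px)   # pixel-centre x in nm
    yc <- index_to_nm(seq_len(nr), px)
    s2 <- 2 * render$psf_sigma_nm^2
    half <- ceiling(6 * render$psf_sigma_nm / px)
    for (k in seq_len(nrow(points))) {
      ci <- nm_to_index(points$x_nm[k], px)
      ri <- nm_to_index(points$y_nm[k], px)
      cs <- max(1L, ci - half):min(nc, ci + half)
      rs <- max(1L, ri - half):min(nr, ri + half)
      gx <- exp(-(xc[cs] - points$x_nm[k])^2 / s2)
      gy <- exp(-(yc[rs] - points$y_nm[k])^2 / s2)
      blobs[rs, cs] <- blobs[rs, cs] + outer(gy, gx)
    }
  } else if (nrow(points) > 0) {
    # psf 0: a single-pixel impulse per point
    idx <- cbind(nm_to_index(points$y_nm, px), nm_to_index(points$x_nm, px))
    for (k in seq_len(nrow(idx))) blobs[idx[k, 1], idx[k, 2]] <-
        blobs[idx[k, 1], idx[k, 2]] + 1
  }
  sign <- if (render$polarity == "dark_filaments") -1 else 1
  img <- render$background_level + sign * render$contrast * blobs
  if (render$noise_sd > 0) {
    img <- img + with_seed(render$seed,
                           matrix(rnorm(nr * nc, 0, render$noise_sd), nr, nc))
  }
  tm_image(pmin(pmax(img, 0), 1), px)
}
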