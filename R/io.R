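## File I/O: TIFF images/volumes with JSON calibration sidecars, CSV point
## sets and truth tables.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' Write a calibrated image as TIFF plus JSON sidecar
#'
#' Intensities are written as 32-bit float samples; the calibration goes to
#' `<name>.json` as `{"pixel_size_nm": ...}`.
#'
#' @param image A [tm_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "tm_image"))
  tiff::writeTIFF(pmin(pmax(image$pixels, 0), 1), path,
                  bits.per.sample = 32)
  jsonlite::write_json(list(pixel_size_nm = image$pixel_size_nm),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image written by [write_image_tiff()]
#'
#' @param path TIFF path with an accompanying `.json` sidecar.
#' @return A [tm_image()].
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such image: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(sprintf("missing calibration sidecar: %s", sc))
  meta <- jsonlite::read_json(sc)
  tm_image(tiff::readTIFF(path), meta$pixel_size_nm)
}

#' Write a binary volume as multi-page TIFF plus JSON sidecar
#'
#' One 8-bit page per z slice (page z holds `voxels[, , z]` transposed to
#' row = y); the sidecar stores `voxel_size_nm` and `channel`.
#'
#' @param volume A [tm_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "tm_volume"))
  pages <- purrr::map(seq_len(dim(volume$voxels)[3]), function(z) {
    t(volume$voxels[, , z]) * 1
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  jsonlite::write_json(list(voxel_size_nm = volume$voxel_size_nm,
                            channel = volume$channel),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF path with an accompanying `.json` sidecar.
#' @return A [tm_volume()].
#' @export
read_volume_tiff <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such volume: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(sprintf("missing calibration sidecar: %s", sc))
  meta <- jsonlite::read_json(sc)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- array(FALSE, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                              length(pages)))
  for (z in seq_along(pages)) vox[, , z] <- t(pages[[z]]) > 0.5
  tm_volume(vox, unlist(meta$voxel_size_nm),
            channel = meta$channel %||% "actin")
}

#' Write a point set (or any tibble) as CSV with header
#'
#' @param points Tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  readr::write_csv(points, path)
  invisible(path)
}

#' Read a point-set CSV
#'
#' @param path CSV path with at least `x_nm`, `y_nm` columns.
#' @return A tibble; an `id` column is added when absent.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such point file: %s", path))
  pts <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(pts))) {
    abort(sprintf("%s lacks x_nm/y_nm columns", path))
  }
  if (!"id" %in% names(pts)) pts <- dplyr::mutate(pts,
                                                  id = dplyr::row_number())
  pts
}
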