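## broom-style tidiers for fitted objects and result containers.

#' Tidy a profile fit
#'
#' @param x A `tm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.tm_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a profile fit
#'
#' @param x A `tm_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `rss`, `converged`, `peak_position_um`,
#'   `bottom`, `top` (plateaus, `NA` unless four-parameter logistic) and
#'   `n`.
#' @exportS3Method generics::glance
glance.tm_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, converged = x$converged,
         peak_position_um = x$peak_position_um,
         bottom = unname(x$plateaus["bottom"] %||% NA_real_)[1],
         top = unname(x$plateaus["top"] %||% NA_real_)[1],
         n = nrow(x$data))
}

#' Tidy a packing summary into its triplet-angle records
#'
#' @param x A `tm_packing` (from [summarize_packing()]).
#' @param ... Unused.
#' @return A tibble with one row per triplet angle.
#' @exportS3Method generics::tidy
tidy.tm_packing <- function(x, ...) {
  tibble(angle_deg = x$triplet_angles_deg[[1]])
}

#' One-row summary of a packing analysis
#'
#' @param x A `tm_packing`.
#' @param ... Unused.
#' @return The scalar columns of the summary as a plain tibble.
#' @exportS3Method generics::glance
glance.tm_packing <- function(x, ...) {
  dplyr::select(as_tibble(x), "n_points", "median_nn_distance_nm",
                "median_triplet_angle_deg", "estimated_spacing_nm",
                "bundle_diameter_nm")
}

#' Tidy an interaction result into its segments
#'
#' @param x A `tm_interaction`.
#' @param ... Unused.
#' @return The segment tibble (`trace_id`, `start`, `end`, `length_um`).
#' @exportS3Method generics::tidy
tidy.tm_interaction <- function(x, ...) x$segments

#' One-row summary of an interaction analysis
#'
#' @param x A `tm_interaction`.
#' @param ... Unused.
#' @return A tibble with totals and `percent_interacting`.
#' @exportS3Method generics::glance
glance.tm_interaction <- function(x, ...) {
  tibble(dilation_radius_vox = x$dilation_radius_vox,
         n_segments = nrow(x$segments),
         median_segment_um = if (nrow(x$segments))
           median_mid(x$segments$length_um) else NA_real_,
         total_interacting_actin_um = x$total_interacting_actin_um,
         total_actin_um = x$total_actin_um,
         percent_interacting = x$percent_interacting)
}

#' Tidy a depth-area result
#'
#' @param x A `tm_depth_area`.
#' @param ... Unused.
#' @return The per-depth area tibble.
#' @exportS3Method generics::tidy
tidy.tm_depth_area <- function(x, ...) x$table

#' One-row summary of a depth-area regression
#'
#' @param x A `tm_depth_area`.
#' @param ... Unused.
#' @return A tibble with the two slopes (um^2 per um of depth).
#' @exportS3Method generics::glance
glance.tm_depth_area <- function(x, ...) {
  tibble(slope_cell = x$slope_cell, slope_bundle = x$slope_bundle)
}
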