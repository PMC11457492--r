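## Filament/bundle packing statistics: centre detection, the 12-nm
## neighbour graph, triplet packing angles and per-bundle summaries.

#' Detect filament (or bundle) centres in a calibrated image
#'
#' Blob detection by scale-normalised Laplacian of Gaussian at a scale
#' matched to half the expected spacing, polarity aware, followed by
#' subpixel refinement by separable parabolic interpolation of the LoG
#' response around each maximum. (A windowed intensity centroid is biased
#' toward neighbouring blobs at lattice densities; the three-point parabola
#' is local and unbiased for symmetric blobs.)
#'
#' @param image A [tm_image()].
#' @param expected_spacing_nm Expected centre-to-centre distance; must exceed
#'   twice the pixel size.
#' @param polarity Whether filaments are dark (TEM-like, default) or bright.
#' @param rel_threshold Minimum LoG response of an accepted detection, as a
#'   fraction of the strongest response.
#' @return A tibble with columns `id`, `x_nm`, `y_nm`. A flat image yields
#'   zero rows with a warning, not an error.
#' @export
detect_centers <- function(image, expected_spacing_nm,
                           polarity = c("dark_filaments", "bright_filaments"),
                           rel_threshold = 0.2) {
  stopifnot(inherits(image, "tm_image"))
  polarity <- match.arg(polarity)
  px <- image$pixel_size_nm
  if (expected_spacing_nm <= 2 * px) {
    abort("`expected_spacing_nm` must exceed twice the pixel size.")
  }
  s <- if (polarity == "dark_filaments") -image$pixels else image$pixels
  if (diff(range(s)) < 1e-12) {
    warn("flat image: no extrema, returning an empty point set")
    return(tibble(id = integer(0), x_nm = numeric(0), y_nm = numeric(0)))
  }
  sigma_px <- (expected_spacing_nm / (2 * sqrt(2))) / px
  sm <- EBImage::gblur(s, sigma = sigma_px)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- -sigma_px^2 * EBImage::filter2(sm, lap)
  resp <- as.matrix(resp)

  nr <- nrow(resp); nc <- ncol(resp)
  # strict 8-neighbour local maxima (interior pixels only)
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > resp[1:(nr - 2), 2:(nc - 1)] &
    core > resp[3:nr, 2:(nc - 1)] &
    core > resp[2:(nr - 1), 1:(nc - 2)] &
    core > resp[2:(nr - 1), 3:nc] &
    core > resp[1:(nr - 2), 1:(nc - 2)] &
    core > resp[1:(nr - 2), 3:nc] &
    core > resp[3:nr, 1:(nc - 2)] &
    core > resp[3:nr, 3:nc] &
    core > 0
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warn("no blob-like extrema found, returning an empty point set")
    return(tibble(id = integer(0), x_nm = numeric(0), y_nm = numeric(0)))
  }
  idx <- idx + 1L  # back to full-image indices
  mag <- resp[idx]
  keep <- mag >= rel_threshold * max(mag)
  idx <- idx[keep, , drop = FALSE]; mag <- mag[keep]

  # greedy non-maximum suppression at half the expected spacing
  ord <- order(mag, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; mag <- mag[ord]
  min_sep_px <- (expected_spacing_nm / 2) / px
  taken <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    if (k == 1) { taken[1] <- TRUE; next }
    prev <- idx[taken, , drop = FALSE]
    d2 <- (prev[, 1] - idx[k, 1])^2 + (prev[, 2] - idx[k, 2])^2
    if (all(d2 > min_sep_px^2)) taken[k] <- TRUE
  }
  idx <- idx[taken, , drop = FALSE]

  # subpixel refinement: separable 3-point parabolic interpolation
  parab <- function(a, b, c) {
    den <- a - 2 * b + c
    if (abs(den) < 1e-12) 0 else pmin(pmax(0.5 * (a - c) / den, -0.5), 0.5)
  }
  cx <- numeric(nrow(idx)); cy <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    ri <- idx[k, 1]; ci <- idx[k, 2]
    dr <- if (ri > 1 && ri < nr) {
      parab(resp[ri - 1, ci], resp[ri, ci], resp[ri + 1, ci])
    } else 0
    dc <- if (ci > 1 && ci < nc) {
      parab(resp[ri, ci - 1], resp[ri, ci], resp[ri, ci + 1])
    } else 0
    cy[k] <- ri + dr; cx[k] <- ci + dc
  }
  out <- tibble(id = seq_along(cx),
                x_nm = index_to_nm(cx, px),
                y_nm = index_to_nm(cy, px))
  dplyr::arrange(out, .data$y_nm, .data$x_nm) |>
    dplyr::mutate(id = dplyr::row_number())
}

#' Build the radius-bounded neighbour graph of a point set
#'
#' Edge `(i, j)` exists iff `0 < dist(i, j) <= radius_nm` (centre-to-centre
#' Euclidean distance). The default radius is the 12-nm rule used for actin
#' filaments, roughly twice the width of a single filament.
#'
#' @param points Tibble with `id`, `x_nm`, `y_nm`.
#' @param radius_nm Neighbour radius in nm (default 12).
#' @return A tibble of edges `i`, `j` (with `i < j`), `distance_nm`; the
#'   radius is attached as attribute `radius_nm`.
#' @export
build_neighbor_graph <- function(points, radius_nm = 12) {
  assert_scalar_pos(radius_nm, "radius_nm")
  if (nrow(points) < 1) abort("need at least one point")
  co <- cbind(points$x_nm, points$y_nm)
  d <- as.matrix(stats::dist(co))
  ut <- which(upper.tri(d) & d <= radius_nm & d > 0, arr.ind = TRUE)
  out <- tibble(i = points$id[ut[, 1]],
                j = points$id[ut[, 2]],
                distance_nm = d[ut])
  out <- dplyr::arrange(out, .data$i, .data$j)
  attr(out, "radius_nm") <- radius_nm
  out
}

# degree of every point (including isolated ones), in points$id order
graph_degrees <- function(points, graph) {
  tab <- table(factor(c(graph$i, graph$j), levels = points$id))
  as.integer(tab)
}

#' Triplet packing angles at each focal point
#'
#' For every point with at least two neighbours in the graph, neighbours are
#' sorted by azimuth about the focal point and the angle subtended at the
#' focal point by each azimuth-consecutive pair is emitted (including the
#' wrap-around pair only when the degree is at least 3). On an ideal
#' hexagonal lattice every interior focal point contributes six angles of 60
#' degrees, which is the diagnostic of hexagonal packing.
#'
#' @param points Tibble with `id`, `x_nm`, `y_nm`.
#' @param graph Edge tibble from [build_neighbor_graph()] built on the same
#'   points.
#' @return A tibble with `focal_id` and `angle_deg` (angles in (0, 180],
#'   computed as the arccosine of the normalised dot product).
#' @export
triplet_angles <- function(points, graph) {
  if (nrow(graph) == 0) {
    return(tibble(focal_id = integer(0), angle_deg = numeric(0)))
  }
  adj <- dplyr::bind_rows(
    dplyr::select(graph, focal = "i", nb = "j"),
    dplyr::select(graph, focal = "j", nb = "i"))
  lookup <- cbind(points$x_nm, points$y_nm)
  rownames(lookup) <- as.character(points$id)
  res <- adj |>
    dplyr::group_by(.data$focal) |>
    dplyr::group_map(function(df, key) {
      focal <- key$focal
      if (nrow(df) < 2) return(NULL)
      f <- lookup[as.character(focal), ]
      v <- lookup[as.character(df$nb), , drop = FALSE]
      v <- sweep(v, 2, f)
      az <- atan2(v[, 2], v[, 1])
      o <- order(az)
      v <- v[o, , drop = FALSE]
      k <- nrow(v)
      pairs <- if (k == 2) cbind(1, 2) else cbind(seq_len(k), c(2:k, 1))
      ang <- vapply(seq_len(nrow(pairs)), function(p) {
        a <- v[pairs[p, 1], ]; b <- v[pairs[p, 2], ]
        ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
        acos(pmin(pmax(ct, -1), 1)) * 180 / pi
      }, numeric(1))
      tibble(focal_id = focal, angle_deg = ang)
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) tibble(focal_id = integer(0), angle_deg = numeric(0))
  else res
}

## --- minimum enclosing circle (Welzl, move-to-front) -----------------------

circle_from2 <- function(a, b) {
  c(centre = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
}

circle_from3 <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  c(centre = ctr, r = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ[1:2])^2)) <= circ[3] * (1 + tol) + tol
}

trivial_circle <- function(boundary) {
  n <- length(boundary)
  if (n == 0) return(c(0, 0, 0))
  if (n == 1) return(c(boundary[[1]], 0))
  if (n == 2) return(circle_from2(boundary[[1]], boundary[[2]]))
  # three points: try the pairwise circles first, else circumcircle
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    circ <- circle_from2(boundary[[pair[1]]], boundary[[pair[2]]])
    third <- boundary[[setdiff(1:3, pair)]]
    if (in_circle(circ, third)) return(circ)
  }
  circle_from3(boundary[[1]], boundary[[2]], boundary[[3]]) %||% c(0, 0, Inf)
}

#' Minimum enclosing circle of a 2D point set
#'
#' Welzl's randomised algorithm; exact up to floating point.
#'
#' @param coords Two-column matrix of coordinates.
#' @return Named numeric vector `x`, `y`, `radius`.
#' @export
min_enclosing_circle <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) abort("no points")
  pts <- lapply(seq_len(nrow(coords)), function(i) as.numeric(coords[i, ]))
  pts <- with_seed(7L, sample(pts))
  circ <- c(pts[[1]], 0)
  for (i in seq_along(pts)) {
    if (in_circle(circ, pts[[i]])) next
    circ <- c(pts[[i]], 0)
    for (j in seq_len(i - 1)) {
      if (in_circle(circ, pts[[j]])) next
      circ <- circle_from2(pts[[i]], pts[[j]])
      for (k in seq_len(j - 1)) {
        if (in_circle(circ, pts[[k]])) next
        circ <- circle_from3(pts[[i]], pts[[j]], pts[[k]]) %||%
          trivial_circle(list(pts[[i]], pts[[j]], pts[[k]]))
      }
    }
  }
  c(x = circ[[1]], y = circ[[2]], radius = circ[[3]])
}

#' Summarise the packing of a filament (or bundle) point set
#'
#' Computes the per-bundle quantities reported for tuft-cell cross-sections:
#' point count, the neighbour-degree histogram, median neighbour distance,
#' the triplet-angle distribution, the estimated lattice spacing (median
#' distance over all neighbour-graph edges, which is unbiased under
#' positional jitter where the per-point nearest-neighbour minimum is biased
#' low; point sets with no edges fall back to the median unbounded
#' nearest-neighbour distance so sparse inputs still get an estimate) and
#' the bundle diameter (minimum enclosing circle
#' of the centres plus one estimated spacing, accounting for filament
#' extent). Medians use the midpoint convention for even counts.
#'
#' @param points Tibble with `id`, `x_nm`, `y_nm`.
#' @param graph Edge tibble from [build_neighbor_graph()].
#' @return A one-row tibble of class `tm_packing` with columns `n_points`,
#'   `median_nn_distance_nm`, `median_triplet_angle_deg`,
#'   `estimated_spacing_nm`, `bundle_diameter_nm`, and list-columns
#'   `nn_count_histogram` (tibble `degree`, `count`) and
#'   `triplet_angles_deg`.
#' @export
summarize_packing <- function(points, graph) {
  if (nrow(points) == 0) abort("empty point set")
  deg <- graph_degrees(points, graph)
  hist_tb <- tibble(degree = as.integer(names(table(deg))),
                    count = as.integer(table(deg)))
  # per-point nearest neighbour within the graph (NA when isolated)
  nn_graph <- if (nrow(graph) > 0) {
    dplyr::bind_rows(
      dplyr::select(graph, id = "i", d = "distance_nm"),
      dplyr::select(graph, id = "j", d = "distance_nm")) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(nn = min(.data$d)) |>
      dplyr::pull(.data$nn)
  } else numeric(0)
  # spacing: median neighbour-graph edge length; unbounded NN fallback
  spacing <- if (nrow(graph) > 0) {
    median_mid(graph$distance_nm)
  } else if (nrow(points) > 1) {
    d <- as.matrix(stats::dist(cbind(points$x_nm, points$y_nm)))
    diag(d) <- Inf
    median_mid(apply(d, 1, min))
  } else NA_real_
  ang <- triplet_angles(points, graph)
  mec <- min_enclosing_circle(cbind(points$x_nm, points$y_nm))
  diam <- 2 * mec[["radius"]] + ifelse(is.na(spacing), 0, spacing)
  out <- tibble(
    n_points = nrow(points),
    median_nn_distance_nm = if (length(nn_graph)) median_mid(nn_graph)
                            else NA_real_,
    median_triplet_angle_deg = if (nrow(ang)) median_mid(ang$angle_deg)
                               else NA_real_,
    estimated_spacing_nm = spacing,
    bundle_diameter_nm = diam,
    nn_count_histogram = list(hist_tb),
    triplet_angles_deg = list(ang$angle_deg))
  class(out) <- c("tm_packing", class(out))
  out
}
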