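## 3D network quantification: polymer tracing, pitch, dilation-overlap
## interaction between actin and microtubule channels, area versus depth,
## and apical shape descriptors.

# 26-neighbourhood offsets (excluding the origin)
offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# Build the 26-adjacency graph of the on-voxels; returns voxel coordinates
# and an igraph whose vertex order matches the coordinate rows.
voxel_graph <- function(vox) {
  d <- dim(vox)
  lin <- which(vox)
  if (length(lin) == 0) return(NULL)
  co <- arrayInd(lin, d)
  pos <- integer(prod(d)); pos[lin] <- seq_along(lin)
  edges <- list()
  for (k in seq_len(nrow(offsets26))) {
    o <- offsets26[k, ]
    sh <- cbind(co[, 1] + o[1], co[, 2] + o[2], co[, 3] + o[3])
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    lin2 <- (sh[ok, 3] - 1) * d[1] * d[2] + (sh[ok, 2] - 1) * d[1] + sh[ok, 1]
    nb <- pos[lin2]
    src <- which(ok)[nb > 0]
    tgt <- nb[nb > 0]
    keep <- src < tgt  # undirected, once
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(src[keep], tgt[keep])
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), ncol = 2)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
  list(coords = co, graph = g)
}

#' Pitch of a polymer path relative to the apicobasal axis
#'
#' The principal axis of the calibrated path points (dominant eigenvector of
#' their covariance) is projected on the z axis;
#' `pitch = asin(|v_z| / |v|)` in degrees, so a vertical polymer scores 90
#' and a horizontal one 0. The principal axis is robust to voxel jitter in
#' traced skeletons; the end-to-end direction gives the same answer for
#' straight polymers.
#'
#' @param path_vox Matrix of voxel indices `(x, y, z)`, one row per voxel,
#'   with at least two distinct points.
#' @param voxel_size_nm Length-3 calibration `(x, y, z)` nm.
#' @return Pitch in degrees, in `[0, 90]`.
#' @export
pitch_of <- function(path_vox, voxel_size_nm) {
  p <- sweep(as.matrix(path_vox), 2, as.numeric(voxel_size_nm), `*`)
  p <- sweep(p, 2, colMeans(p))
  if (all(abs(p) < 1e-12)) abort("all path points identical")
  v <- eigen(crossprod(p), symmetric = TRUE)$vectors[, 1]
  asin(abs(v[3]) / sqrt(sum(v^2))) * 180 / pi
}

#' Trace polymers in a binary 3D volume
#'
#' Labels 26-connected components, reduces each to its longest geodesic path
#' through the voxel adjacency graph (a 1-voxel-wide centreline; exact for
#' the straight, thin polymers this package generates and analyses), and
#' reports calibrated length and pitch per trace. Components shorter than
#' `min_length_um` are discarded.
#'
#' @param mask A [tm_volume()].
#' @param min_length_um Minimum trace length retained (default 0.5 um).
#' @return A tibble of class `tm_traces` with columns `id`, `n_vox`,
#'   `length_um`, `pitch_deg`, `pitch_end_to_end_deg` and list-column
#'   `path_vox` (matrix of voxel indices along the trace).
#' @export
trace_polymers <- function(mask, min_length_um = 0.5) {
  stopifnot(inherits(mask, "tm_volume"))
  vg <- voxel_graph(mask$voxels)
  out_empty <- tibble(id = integer(0), n_vox = integer(0),
                      length_um = numeric(0), pitch_deg = numeric(0),
                      pitch_end_to_end_deg = numeric(0),
                      path_vox = list())
  class(out_empty) <- c("tm_traces", class(out_empty))
  if (is.null(vg)) return(out_empty)
  vs <- mask$voxel_size_nm
  comp <- igraph::components(vg$graph)
  rows <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(vg$graph, vids)
    co <- vg$coords[vids, , drop = FALSE]
    # geodesic edge weights in nm
    el <- igraph::as_edgelist(sub, names = FALSE)
    if (nrow(el) > 0) {
      wts <- sqrt(rowSums((sweep(co[el[, 1], , drop = FALSE] -
                                   co[el[, 2], , drop = FALSE],
                                 2, vs, `*`))^2))
      igraph::E(sub)$weight <- wts
    }
    # double-sweep: farthest vertex from an arbitrary start, then farthest
    # from that; the geodesic between them is the centreline
    if (igraph::vcount(sub) == 1) {
      path_local <- 1L
    } else {
      d1 <- igraph::distances(sub, v = 1)[1, ]
      a <- which.max(ifelse(is.finite(d1), d1, -1))
      d2 <- igraph::distances(sub, v = a)[1, ]
      b <- which.max(ifelse(is.finite(d2), d2, -1))
      path_local <- as.integer(
        igraph::shortest_paths(sub, from = a, to = b)$vpath[[1]])
    }
    path <- co[path_local, , drop = FALSE]
    len_um <- if (nrow(path) > 1) {
      steps <- sweep(diff(path), 2, vs, `*`)
      sum(sqrt(rowSums(steps^2))) / 1000
    } else 0
    if (len_um < min_length_um) next
    ete <- sweep(path[nrow(path), , drop = FALSE] - path[1, , drop = FALSE],
                 2, vs, `*`)
    pitch_ete <- asin(abs(ete[3]) / sqrt(sum(ete^2))) * 180 / pi
    rows[[length(rows) + 1L]] <- tibble(
      id = length(rows) + 1L, n_vox = length(vids), length_um = len_um,
      pitch_deg = pitch_of(path, vs),
      pitch_end_to_end_deg = pitch_ete,
      path_vox = list(path))
  }
  if (!length(rows)) return(out_empty)
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tm_traces", class(out))
  out
}

#' Iterated unit-ball dilation of a 3D mask
#'
#' Dilates with the radius-1 digital Euclidean ball (the 6-neighbour cross),
#' applied `iterations` times, following the convention of iterated unit
#' dilations used in FIJI.
#'
#' @param vox Logical 3D array.
#' @param iterations Number of unit dilations (0 returns the input).
#' @return Logical 3D array.
#' @export
dilate3d <- function(vox, iterations = 4L) {
  d <- dim(vox)
  for (it in seq_len(iterations)) {
    out <- vox
    out[-1, , ] <- out[-1, , ] | vox[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | vox[-1, , ]
    out[, -1, ] <- out[, -1, ] | vox[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | vox[, -1, ]
    out[, , -1] <- out[, , -1] | vox[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | vox[, , -1]
    vox <- out
  }
  vox
}

#' Actin-microtubule interaction by dilation overlap
#'
#' Marks the actin skeleton voxels lying within the dilation reach of the
#' microtubule channel (equivalent, for the symmetric ball element, to
#' dilating the actin and measuring overlap with microtubules, but measured
#' along the actin so the interaction length denominator is the total actin
#' length). Contiguous interacting runs along each trace form segments; runs
#' separated by at most `gap_merge_vox` skeleton voxels are merged to bridge
#' single-voxel dropouts.
#'
#' @param actin,mt [tm_volume()]s with identical shape and calibration.
#' @param dilation_radius_vox Iterations of the unit-ball dilation
#'   (default 4).
#' @param traces Optional precomputed `tm_traces` for the actin channel.
#' @param gap_merge_vox Maximum run gap (in skeleton voxels) merged into one
#'   segment.
#' @param min_length_um Passed to [trace_polymers()] when `traces` is NULL.
#' @return An object of class `tm_interaction`: list with `segments` (tibble
#'   `trace_id`, `start`, `end`, `length_um`), `dilation_radius_vox`,
#'   `total_interacting_actin_um`, `total_actin_um`, `percent_interacting`.
#' @export
interaction_map <- function(actin, mt, dilation_radius_vox = 4L,
                            traces = NULL, gap_merge_vox = 2L,
                            min_length_um = 0.5) {
  stopifnot(inherits(actin, "tm_volume"), inherits(mt, "tm_volume"))
  if (!identical(dim(actin$voxels), dim(mt$voxels)) ||
      !isTRUE(all.equal(actin$voxel_size_nm, mt$voxel_size_nm))) {
    abort("actin and microtubule volumes must share shape and calibration")
  }
  if (dilation_radius_vox < 1) abort("`dilation_radius_vox` must be >= 1")
  if (is.null(traces)) traces <- trace_polymers(actin, min_length_um)
  reach <- dilate3d(mt$voxels, dilation_radius_vox)
  vs <- actin$voxel_size_nm
  segs <- list()
  total_actin <- 0; total_inter <- 0
  for (k in seq_len(nrow(traces))) {
    path <- traces$path_vox[[k]]
    n <- nrow(path)
    total_actin <- total_actin + traces$length_um[k]
    flag <- reach[path]
    if (!any(flag)) next
    # merge runs separated by <= gap_merge_vox off-voxels
    on <- which(flag)
    brk <- which(diff(on) > gap_merge_vox + 1L)
    starts <- on[c(1L, brk + 1L)]
    ends <- on[c(brk, length(on))]
    for (s in seq_along(starts)) {
      i0 <- starts[s]; i1 <- ends[s]
      len_um <- if (i1 > i0) {
        steps <- sweep(diff(path[i0:i1, , drop = FALSE]), 2, vs, `*`)
        sum(sqrt(rowSums(steps^2))) / 1000
      } else {
        mean(vs) / 1000  # single-voxel contact counts one voxel pitch
      }
      total_inter <- total_inter + len_um
      segs[[length(segs) + 1L]] <- tibble(
        trace_id = traces$id[k], start = i0, end = i1, length_um = len_um)
    }
  }
  seg_tb <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble(trace_id = integer(0), start = integer(0), end = integer(0),
           length_um = numeric(0))
  pct <- if (total_actin > 0) 100 * total_inter / total_actin else 0
  structure(list(segments = seg_tb,
                 dilation_radius_vox = as.integer(dilation_radius_vox),
                 total_interacting_actin_um = total_inter,
                 total_actin_um = total_actin,
                 percent_interacting = pct),
            class = "tm_interaction")
}

#' @export
print.tm_interaction <- function(x, ...) {
  cat(sprintf(
    "<tm_interaction> dilation %d vox: %.2f of %.2f um actin interacting (%.1f%%), %d segment(s)\n",
    x$dilation_radius_vox, x$total_interacting_actin_um, x$total_actin_um,
    x$percent_interacting, nrow(x$segments)))
  invisible(x)
}

# Convex hull area (um^2) of the on-pixels of a 2D slice, taking each pixel
# as a unit square (so a single pixel contributes its own area).
hull_area_um2 <- function(slice, pixel_area_um2, pitch_xy_um) {
  idx <- which(slice, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  corners <- rbind(
    cbind(idx[, 1] - 1, idx[, 2] - 1), cbind(idx[, 1], idx[, 2] - 1),
    cbind(idx[, 1] - 1, idx[, 2]), cbind(idx[, 1], idx[, 2]))
  corners <- unique(corners)
  xy <- cbind(corners[, 1] * pitch_xy_um[1], corners[, 2] * pitch_xy_um[2])
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Bundle and cell cross-sectional area versus depth
#'
#' For each requested depth below the apical surface (the first z slice
#' containing any cell voxel), the cell area is the on-voxel count times the
#' pixel area and the bundle area is the area of the 2D convex hull of the
#' bundle voxels in that slice (the area occupied by bundles, not the summed
#' bundle cross-sections). Slopes are ordinary least squares of area on
#' depth.
#'
#' @param cell,bundle [tm_volume()]s sharing geometry.
#' @param depths_um Depths below the apical surface (default 0, 1.5, 3,
#'   4.5 um).
#' @return An object of class `tm_depth_area`: list with `table` (tibble
#'   `depth_um`, `cell_area_um2`, `bundle_area_um2`), `slope_cell`,
#'   `slope_bundle` (um^2 per um depth).
#' @export
area_vs_depth <- function(cell, bundle, depths_um = c(0, 1.5, 3, 4.5)) {
  stopifnot(inherits(cell, "tm_volume"), inherits(bundle, "tm_volume"))
  if (!identical(dim(cell$voxels), dim(bundle$voxels))) {
    abort("cell and bundle volumes must share shape")
  }
  d <- dim(cell$voxels)
  vs <- cell$voxel_size_nm
  zprofile <- vapply(seq_len(d[3]), function(z) any(cell$voxels[, , z]),
                     logical(1))
  if (!any(zprofile)) abort("cell mask is empty")
  z0 <- which(zprofile)[1]
  z_idx <- z0 + round(depths_um * 1000 / vs[3])
  if (any(z_idx < 1 | z_idx > d[3])) {
    abort(sprintf("depth(s) %s um fall outside the volume",
                  paste(depths_um[z_idx < 1 | z_idx > d[3]], collapse = ", ")))
  }
  px_area <- vs[1] * vs[2] / 1e6                 # um^2 per pixel
  pitch_xy <- vs[1:2] / 1000
  tb <- purrr::map2_dfr(depths_um, z_idx, function(dep, z) {
    tibble(depth_um = dep,
           cell_area_um2 = sum(cell$voxels[, , z]) * px_area,
           bundle_area_um2 = hull_area_um2(bundle$voxels[, , z],
                                           px_area, pitch_xy))
  })
  slope_of <- function(y) unname(coef(lm(y ~ tb$depth_um))[2])
  structure(list(table = tb,
                 slope_cell = slope_of(tb$cell_area_um2),
                 slope_bundle = slope_of(tb$bundle_area_um2)),
            class = "tm_depth_area")
}

#' @export
print.tm_depth_area <- function(x, ...) {
  print(x$table)
  cat(sprintf("slope cell %.3f, slope bundle %.3f um^2/um\n",
              x$slope_cell, x$slope_bundle))
  invisible(x)
}

# Closed contour(s) of a binary mask at level 0.5, optionally smoothed by a
# circular moving average of the polygon vertices.
mask_perimeter <- function(mask, pixel_size, smooth_window = 3L) {
  cl <- grDevices::contourLines(seq_len(nrow(mask)), seq_len(ncol(mask)),
                                mask * 1, levels = 0.5)
  if (!length(cl)) return(NA_real_)
  per <- 0
  for (cc in cl) {
    x <- cc$x; y <- cc$y
    n0 <- length(x)
    if (abs(x[1] - x[n0]) < 1e-9 && abs(y[1] - y[n0]) < 1e-9) {
      x <- x[-1]; y <- y[-1]
    }
    n <- length(x)
    if (smooth_window > 1 && n > smooth_window) {
      k <- (smooth_window - 1) %/% 2
      wrap <- function(i) ((i - 1) %% n) + 1
      xs <- vapply(seq_len(n), function(i) mean(x[wrap((i - k):(i + k))]),
                   numeric(1))
      ys <- vapply(seq_len(n), function(i) mean(y[wrap((i - k):(i + k))]),
                   numeric(1))
      x <- xs; y <- ys
    }
    per <- per + sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  }
  per * pixel_size
}

#' Apical shape descriptors of a single cell outline
#'
#' Area from the pixel count and perimeter from the smoothed
#' marching-squares contour, combined into the circularity
#' `4 * pi * area / perimeter^2` (1 for a perfect circle).
#'
#' @param boundary 2D logical mask of the apical region; must contain
#'   exactly one connected component.
#' @param pixel_size_um Pixel edge in um.
#' @param smooth_window Odd contour-smoothing window (vertices); 1 disables
#'   smoothing.
#' @return A one-row tibble with `area_um2`, `perimeter_um`, `circularity`.
#' @export
apical_shape <- function(boundary, pixel_size_um, smooth_window = 3L) {
  if (!any(boundary)) abort("empty region")
  ncomp <- max(EBImage::bwlabel(boundary * 1))
  if (ncomp != 1) {
    abort(sprintf("expected a single connected region, found %d", ncomp))
  }
  area <- sum(boundary) * pixel_size_um^2
  per <- mask_perimeter(boundary, pixel_size_um, smooth_window)
  tibble(area_um2 = area, perimeter_um = per,
         circularity = 4 * pi * area / per^2)
}
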