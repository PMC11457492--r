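# Independent reference implementations (plain loops, no package internals)
# and shared fixtures.

# The 7-point hexagonal rosette: a centre plus its six-ring at distance d.
rosette_points <- function(d = 9, centre = c(30, 30)) {
  th <- (0:5) * pi / 3
  tibble::tibble(id = 1:7,
                 x_nm = centre[1] + c(0, d * cos(th)),
                 y_nm = centre[2] + c(0, d * sin(th)))
}

# Brute-force neighbour graph: all-pairs double loop.
brute_graph <- function(points, radius) {
  n <- nrow(points)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dd <- sqrt((points$x_nm[i] - points$x_nm[j])^2 +
                   (points$y_nm[i] - points$y_nm[j])^2)
      if (dd > 0 && dd <= radius) {
        out[[length(out) + 1L]] <- c(points$id[i], points$id[j], dd)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          distance_nm = numeric(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                 distance_nm = m[, 3])
}

# Brute-force triplet angles: for each focal point with >= 2 neighbours,
# azimuth-sort neighbours and take consecutive pairs (wrap iff degree >= 3).
brute_angles <- function(points, edges) {
  angles <- numeric(0)
  focals <- integer(0)
  for (f in points$id) {
    nbs <- c(edges$j[edges$i == f], edges$i[edges$j == f])
    if (length(nbs) < 2) next
    fx <- points$x_nm[points$id == f]; fy <- points$y_nm[points$id == f]
    vx <- points$x_nm[match(nbs, points$id)] - fx
    vy <- points$y_nm[match(nbs, points$id)] - fy
    o <- order(atan2(vy, vx))
    vx <- vx[o]; vy <- vy[o]
    k <- length(vx)
    pair_idx <- if (k == 2) list(c(1, 2)) else
      lapply(seq_len(k), function(p) c(p, if (p == k) 1 else p + 1))
    for (pr in pair_idx) {
      a <- c(vx[pr[1]], vy[pr[1]]); b <- c(vx[pr[2]], vy[pr[2]])
      ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      angles <- c(angles, acos(min(max(ct, -1), 1)) * 180 / pi)
      focals <- c(focals, f)
    }
  }
  tibble::tibble(focal_id = focals, angle_deg = angles)
}

# Brute-force enumeration of triangular-lattice sites within a disc.
brute_hex_count <- function(d, radius) {
  m <- ceiling(radius / d) + 2
  count <- 0
  for (i in seq(-2 * m, 2 * m)) {
    for (j in seq(-m, m)) {
      x <- i * d + j * d / 2
      y <- j * d * sqrt(3) / 2
      if (x^2 + y^2 <= radius^2 + 1e-9) count <- count + 1
    }
  }
  count
}

# Direct evaluation of the Gaussian blob-sum image model at a pixel centre.
blob_sum_at <- function(x_nm, y_nm, points, psf_sigma_nm, background,
                        contrast, dark = TRUE) {
  s <- sum(exp(-((points$x_nm - x_nm)^2 + (points$y_nm - y_nm)^2) /
                 (2 * psf_sigma_nm^2)))
  background + (if (dark) -1 else 1) * contrast * s
}

# A rendered rosette image used across packing/Fourier tests.
rosette_image <- function(d = 9, psf = 2, px = 1, noise_sd = 0,
                          shape = c(60, 60), seed = 1) {
  pts <- rosette_points(d)
  rs <- render_spec(pixel_size_nm = px, psf_sigma_nm = psf,
                    noise_sd = noise_sd, image_shape_px = shape,
                    background_level = 0.8, seed = seed)
  list(points = pts, image = render_cross_section(pts, rs))
}

# Straight-column volume fixture: vertical line(s) of n_vox voxels.
column_volume <- function(cols, shape = c(20, 20, 100),
                          voxel = c(100, 100, 100), channel = "actin") {
  vox <- array(FALSE, dim = shape)
  for (cc in cols) vox[cc[1], cc[2], seq_len(cc[3])] <- TRUE
  tm_volume(vox, voxel, channel)
}
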