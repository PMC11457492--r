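#' Specification of a synthetic two-channel 3D cytoskeletal network
#'
#' Generates straight actin "core bundle" and microtubule polymers in a
#' calibrated volume. Pitch is the inclination relative to the xy plane with
#' 90 degrees meaning vertical (parallel to the apicobasal z axis), matching
#' the convention used for tuft-cell bundles; defaults emulate the measured
#' near-vertical organisation (pitch about 81 degrees, lengths 5-12 um).
#'
#' @param volume_shape_vox Length-3 integer `(nx, ny, nz)` voxel counts.
#' @param voxel_size_nm Length-3 `(x, y, z)` voxel pitch in nm.
#' @param n_actin,n_mt Number of actin and microtubule polymers.
#' @param pitch_mean_deg,pitch_sd_deg Mean and SD of the Gaussian pitch
#'   distribution, truncated to (0, 90].
#' @param length_um_range Polymer lengths are drawn uniformly from this
#'   interval (um), which must lie within `[1, 15]`.
#' @param paired_fraction Fraction of microtubules generated co-aligned with
#'   an actin partner (same direction, span and length) at a fixed lateral
#'   offset.
#' @param pair_offset_nm Lateral centre-to-centre offset of paired
#'   microtubules from their actin partner, nm.
#' @param avoid_overlap Resample polymers that come within one voxel of an
#'   existing polymer of the same channel, so connected components map 1:1
#'   onto polymers.
#' @param max_retries Resampling cap per polymer before a hard error (silent
#'   truncation would bias the length ground truth).
#' @param seed Integer seed.
#' @return A list of class `network3d_spec`.
#' @export
network3d_spec <- function(volume_shape_vox = c(200L, 200L, 140L),
                           voxel_size_nm = c(100, 100, 100),
                           n_actin = 50L,
                           n_mt = 50L,
                           pitch_mean_deg = 81.1,
                           pitch_sd_deg = 5,
                           length_um_range = c(5, 12),
                           paired_fraction = 0.5,
                           pair_offset_nm = 200,
                           avoid_overlap = TRUE,
                           max_retries = 100L,
                           seed = 1L) {
  if (pitch_mean_deg <= 0 || pitch_mean_deg > 90) {
    abort("`pitch_mean_deg` must lie in (0, 90].")
  }
  if (length_um_range[1] < 1 || length_um_range[2] > 15 ||
      diff(length_um_range) < 0) {
    abort("`length_um_range` must be an interval within [1, 15].")
  }
  if (paired_fraction < 0 || paired_fraction > 1) {
    abort("`paired_fraction` must lie in [0, 1].")
  }
  assert_scalar_pos(pair_offset_nm, "pair_offset_nm")
  structure(list(volume_shape_vox = as.integer(volume_shape_vox),
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 n_actin = as.integer(n_actin), n_mt = as.integer(n_mt),
                 pitch_mean_deg = pitch_mean_deg, pitch_sd_deg = pitch_sd_deg,
                 length_um_range = as.numeric(length_um_range),
                 paired_fraction = paired_fraction,
                 pair_offset_nm = pair_offset_nm,
                 avoid_overlap = isTRUE(avoid_overlap),
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "network3d_spec")
}

# Rasterize the segment p0 -> p0 + L*u (nm) into 1-based voxel indices.
rasterize_segment <- function(p0, u, len_nm, voxel_size_nm, shape) {
  step <- min(voxel_size_nm) / 2
  t <- unique(c(seq(0, len_nm, by = step), len_nm))
  pos <- cbind(p0[1] + t * u[1], p0[2] + t * u[2], p0[3] + t * u[3])
  idx <- cbind(floor(pos[, 1] / voxel_size_nm[1]) + 1L,
               floor(pos[, 2] / voxel_size_nm[2]) + 1L,
               floor(pos[, 3] / voxel_size_nm[3]) + 1L)
  idx <- idx[!duplicated(idx), , drop = FALSE]
  if (any(idx < 1L) || any(idx[, 1] > shape[1]) || any(idx[, 2] > shape[2]) ||
      any(idx[, 3] > shape[3])) {
    return(NULL)
  }
  idx
}

# TRUE if any candidate voxel is 26-adjacent to (or on) an occupied voxel.
touches_occupied <- function(occ, idx, shape) {
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    sh <- cbind(idx[, 1] + dx, idx[, 2] + dy, idx[, 3] + dz)
    ok <- sh[, 1] >= 1L & sh[, 1] <= shape[1] &
      sh[, 2] >= 1L & sh[, 2] <= shape[2] &
      sh[, 3] >= 1L & sh[, 3] <= shape[3]
    if (any(occ[sh[ok, , drop = FALSE]])) return(TRUE)
  }
  FALSE
}

# Draw from N(mean, sd) truncated to (0, 90], by rejection.
rtrunc_pitch <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > 0 && x <= 90) return(x)
  }
}

# A unit vector perpendicular to u, at a uniformly random roll angle.
perp_unit <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- a - sum(a * u) * u; p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2],
          u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  th <- runif(1, 0, 2 * pi)
  cos(th) * p1 + sin(th) * p2
}

#' Generate a two-channel 3D network volume with ground truth
#'
#' Each polymer is a straight segment rasterized to a 26-connected voxel
#' path. Actin polymers get pitch drawn from a truncated Gaussian and uniform
#' azimuth; a `paired_fraction` of microtubules copy a distinct actin
#' partner's direction and span at a lateral offset, the rest are drawn
#' independently. Start positions are sampled uniformly over the positions at
#' which the whole segment fits in the volume; polymers that collide with an
#' existing same-channel polymer (when `avoid_overlap`) are resampled up to
#' `max_retries` times, then the generator errors.
#'
#' @param spec A [network3d_spec()].
#' @return A list of class `tm_network_sim` with elements `actin` and `mt`
#'   ([tm_volume()]s) and `truth`, a tibble with one row per polymer
#'   (`id`, `channel`, `pitch_deg`, `azimuth_deg`, `length_um`, `paired`,
#'   `partner_id`, and endpoints `x0_nm` ... `z1_nm`).
#' @export
gen_network_volume <- function(spec) {
  stopifnot(inherits(spec, "network3d_spec"))
  shape <- spec$volume_shape_vox
  vs <- spec$voxel_size_nm
  size_nm <- shape * vs

  place_polymer <- function(occ, u, len_nm, forced_start = NULL) {
    # valid start range per axis so the whole segment stays inside
    delta <- len_nm * u
    lo <- pmax(0, -delta)
    hi <- size_nm - pmax(0, delta) - 1e-6
    if (any(lo > hi)) {
      abort(sprintf(
        "volume (%g x %g x %g nm) too small for a %.2f um polymer at this orientation",
        size_nm[1], size_nm[2], size_nm[3], len_nm / 1000))
    }
    p0 <- forced_start %||% (lo + runif(3) * (hi - lo))
    idx <- rasterize_segment(p0, u, len_nm, vs, shape)
    if (is.null(idx)) return(NULL)
    if (spec$avoid_overlap && touches_occupied(occ, idx, shape)) return(NULL)
    list(p0 = p0, idx = idx)
  }

  with_seed(spec$seed, {
    actin_occ <- array(FALSE, dim = shape)
    mt_occ <- array(FALSE, dim = shape)
    rows <- list()
    actin_geo <- list()

    draw_free <- function(occ, channel, id) {
      for (try in seq_len(spec$max_retries + 1L)) {
        pitch <- rtrunc_pitch(spec$pitch_mean_deg, spec$pitch_sd_deg)
        az <- runif(1, 0, 2 * pi)
        len_nm <- runif(1, spec$length_um_range[1],
                        spec$length_um_range[2]) * 1000
        pr <- pitch * pi / 180
        u <- c(cos(pr) * cos(az), cos(pr) * sin(az), sin(pr))
        pl <- place_polymer(occ, u, len_nm)
        if (!is.null(pl)) {
          return(list(pitch = pitch, az = az, len_nm = len_nm, u = u,
                      p0 = pl$p0, idx = pl$idx))
        }
      }
      abort(sprintf("polymer %d (%s): placement failed after %d retries",
                    id, channel, spec$max_retries))
    }

    for (i in seq_len(spec$n_actin)) {
      g <- draw_free(actin_occ, "actin", i)
      actin_occ[g$idx] <- TRUE
      actin_geo[[i]] <- g
      rows[[length(rows) + 1L]] <- tibble(
        id = i, channel = "actin", pitch_deg = g$pitch,
        azimuth_deg = g$az * 180 / pi, length_um = g$len_nm / 1000,
        paired = FALSE, partner_id = NA_integer_,
        x0_nm = g$p0[1], y0_nm = g$p0[2], z0_nm = g$p0[3],
        x1_nm = g$p0[1] + g$len_nm * g$u[1],
        y1_nm = g$p0[2] + g$len_nm * g$u[2],
        z1_nm = g$p0[3] + g$len_nm * g$u[3])
    }

    n_paired <- round(spec$paired_fraction * spec$n_mt)
    partners <- if (n_paired > 0) {
      sample(spec$n_actin, n_paired, replace = n_paired > spec$n_actin)
    } else integer(0)

    for (j in seq_len(spec$n_mt)) {
      id <- spec$n_actin + j
      if (j <= n_paired) {
        pg <- actin_geo[[partners[j]]]
        placed <- NULL
        for (try in seq_len(spec$max_retries + 1L)) {
          off <- spec$pair_offset_nm * perp_unit(pg$u)
          placed <- place_polymer(mt_occ, pg$u, pg$len_nm,
                                  forced_start = pg$p0 + off)
          if (!is.null(placed)) break
        }
        if (is.null(placed)) {
          abort(sprintf(
            "polymer %d (paired microtubule): placement failed after %d retries",
            id, spec$max_retries))
        }
        mt_occ[placed$idx] <- TRUE
        rows[[length(rows) + 1L]] <- tibble(
          id = id, channel = "microtubule", pitch_deg = pg$pitch,
          azimuth_deg = pg$az * 180 / pi, length_um = pg$len_nm / 1000,
          paired = TRUE, partner_id = partners[j],
          x0_nm = placed$p0[1], y0_nm = placed$p0[2], z0_nm = placed$p0[3],
          x1_nm = placed$p0[1] + pg$len_nm * pg$u[1],
          y1_nm = placed$p0[2] + pg$len_nm * pg$u[2],
          z1_nm = placed$p0[3] + pg$len_nm * pg$u[3])
      } else {
        g <- draw_free(mt_occ, "microtubule", id)
        mt_occ[g$idx] <- TRUE
        rows[[length(rows) + 1L]] <- tibble(
          id = id, channel = "microtubule", pitch_deg = g$pitch,
          azimuth_deg = g$az * 180 / pi, length_um = g$len_nm / 1000,
          paired = FALSE, partner_id = NA_integer_,
          x0_nm = g$p0[1], y0_nm = g$p0[2], z0_nm = g$p0[3],
          x1_nm = g$p0[1] + g$len_nm * g$u[1],
          y1_nm = g$p0[2] + g$len_nm * g$u[2],
          z1_nm = g$p0[3] + g$len_nm * g$u[3])
      }
    }

    structure(list(actin = tm_volume(actin_occ, vs, "actin"),
                   mt = tm_volume(mt_occ, vs, "microtubule"),
                   truth = dplyr::bind_rows(rows)),
              class = "tm_network_sim")
  })
}
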