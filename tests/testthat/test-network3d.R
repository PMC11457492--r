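# 3D generation, tracing, pitch, interaction, areas, apical shape.

test_that("a vertical column traces to one polymer with pitch 90", {
  vol <- column_volume(list(c(10, 10, 100)))
  tr <- trace_polymers(vol)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$pitch_deg, 90)
  expect_equal(tr$length_um, 9.9)  # 100 voxels -> 99 steps of 100 nm
})

test_that("two disjoint columns trace to two polymers", {
  vol <- column_volume(list(c(5, 5, 80), c(15, 15, 60)))
  tr <- trace_polymers(vol)
  expect_equal(nrow(tr), 2)
  expect_equal(sort(tr$length_um), c(5.9, 7.9))
})

test_that("components below the minimum length are discarded; empty masks
           give empty traces", {
  vol <- column_volume(list(c(5, 5, 3)))  # 0.2 um, below the 0.5 um floor
  expect_equal(nrow(trace_polymers(vol)), 0)
  empty <- tm_volume(array(FALSE, dim = c(5, 5, 5)), c(100, 100, 100))
  expect_equal(nrow(trace_polymers(empty)), 0)
})

test_that("pitch_of matches analytic directions exactly", {
  vs <- c(100, 100, 100)
  seg <- function(u, n = 60) {
    t(vapply(seq_len(n), function(k) 1 + round((k - 1) * u * 50 / 100),
             numeric(3)))
  }
  expect_equal(pitch_of(rbind(c(1, 1, 1), c(1, 1, 50)), vs), 90)
  expect_equal(pitch_of(rbind(c(1, 1, 1), c(30, 30, 1)), vs), 0)
  expect_equal(pitch_of(rbind(c(1, 1, 1), c(41, 1, 41)), vs), 45,
               tolerance = 1e-9)
  # direction (1, 0, sqrt(3)): pitch = asin(sqrt(3)/2) = 60 degrees
  p <- cbind(1 + 0:39, 1, 1 + sqrt(3) * (0:39))
  expect_equal(pitch_of(p, vs), 60, tolerance = 1e-9)
  expect_error(pitch_of(rbind(c(2, 2, 2), c(2, 2, 2)), vs), "identical")
})

test_that("generated vertical polymer is a single-voxel-wide column with
           exact truth", {
  sp <- network3d_spec(volume_shape_vox = c(30, 30, 80),
                       n_actin = 1, n_mt = 0, pitch_mean_deg = 90,
                       pitch_sd_deg = 0, length_um_range = c(5, 5),
                       paired_fraction = 0, seed = 3)
  net <- gen_network_volume(sp)
  expect_equal(net$truth$pitch_deg, 90)
  on <- which(net$actin$voxels, arr.ind = TRUE)
  expect_equal(length(unique(on[, 1])), 1)
  expect_equal(length(unique(on[, 2])), 1)
})

test_that("paired microtubules copy their partner's direction", {
  sp <- network3d_spec(volume_shape_vox = c(120, 120, 90),
                       n_actin = 12, n_mt = 12, paired_fraction = 1,
                       pair_offset_nm = 500, length_um_range = c(4, 7),
                       seed = 8)
  net <- gen_network_volume(sp)
  tru <- net$truth
  mt <- dplyr::filter(tru, channel == "microtubule")
  expect_true(all(mt$paired))
  for (k in seq_len(nrow(mt))) {
    a <- tru[tru$id == mt$partner_id[k], ]
    u_mt <- c(mt$x1_nm[k] - mt$x0_nm[k], mt$y1_nm[k] - mt$y0_nm[k],
              mt$z1_nm[k] - mt$z0_nm[k])
    u_a <- c(a$x1_nm - a$x0_nm, a$y1_nm - a$y0_nm, a$z1_nm - a$z0_nm)
    cosang <- sum(u_mt * u_a) / sqrt(sum(u_mt^2) * sum(u_a^2))
    expect_equal(cosang, 1, tolerance = 1e-12)
  }
})

test_that("truth pitches recomputed from endpoints match the stored values
           and their median sits near the generator mean", {
  sp <- network3d_spec(volume_shape_vox = c(300, 300, 130),
                       n_actin = 200, n_mt = 0, pitch_mean_deg = 81.1,
                       pitch_sd_deg = 5, length_um_range = c(5, 12),
                       paired_fraction = 0, seed = 21)
  net <- gen_network_volume(sp)
  tru <- net$truth
  recomputed <- with(tru, asin(abs(z1_nm - z0_nm) /
                                 sqrt((x1_nm - x0_nm)^2 +
                                        (y1_nm - y0_nm)^2 +
                                        (z1_nm - z0_nm)^2)) * 180 / pi)
  expect_equal(recomputed, tru$pitch_deg, tolerance = 1e-9)
  expect_lt(abs(median(tru$pitch_deg) - 81.1), 1)
})

test_that("generator output is deterministic in spec + seed", {
  sp <- network3d_spec(volume_shape_vox = c(60, 60, 70), n_actin = 5,
                       n_mt = 5, length_um_range = c(3, 5), seed = 14)
  n1 <- gen_network_volume(sp)
  n2 <- gen_network_volume(sp)
  expect_identical(n1$actin$voxels, n2$actin$voxels)
  expect_identical(n1$truth, n2$truth)
})

test_that("parallel polymers two voxels apart interact over the overlap
           length; far-apart polymers do not", {
  near <- column_volume(list(c(10, 10, 80)))
  partner <- column_volume(list(c(12, 10, 80)), channel = "microtubule")
  res <- interaction_map(near, partner, dilation_radius_vox = 4)
  expect_equal(nrow(res$segments), 1)
  expect_equal(res$percent_interacting, 100)
  expect_equal(res$total_interacting_actin_um, res$total_actin_um)

  far <- column_volume(list(c(10, 10, 80)), shape = c(40, 40, 100))
  mt_far <- column_volume(list(c(32, 32, 80)), shape = c(40, 40, 100),
                          channel = "microtubule")
  res0 <- interaction_map(far, mt_far, dilation_radius_vox = 4)
  expect_equal(nrow(res0$segments), 0)
  expect_equal(res0$percent_interacting, 0)
})

test_that("perpendicular crossing lines give one bounded segment that
           matches a brute-force dilation check", {
  shape <- c(60, 60, 30)
  act <- array(FALSE, dim = shape); act[10:50, 30, 15] <- TRUE
  mtv <- array(FALSE, dim = shape); mtv[30, 10:50, 15] <- TRUE
  actin <- tm_volume(act, c(100, 100, 100), "actin")
  mt <- tm_volume(mtv, c(100, 100, 100), "microtubule")
  res <- interaction_map(actin, mt, dilation_radius_vox = 4)
  expect_equal(nrow(res$segments), 1)
  expect_lte(res$segments$length_um, (2 * 4 + 1) * 0.1)
  # brute force: actin voxels within Manhattan distance 4 of any mt voxel
  on_a <- which(act, arr.ind = TRUE)
  on_m <- which(mtv, arr.ind = TRUE)
  flag <- vapply(seq_len(nrow(on_a)), function(i) {
    any(abs(on_m[, 1] - on_a[i, 1]) + abs(on_m[, 2] - on_a[i, 2]) +
          abs(on_m[, 3] - on_a[i, 3]) <= 4)
  }, logical(1))
  expect_equal(sum(flag), 2 * 4 + 1)
  expect_equal(res$segments$length_um, (sum(flag) - 1) * 0.1)
})

test_that("interaction length is non-decreasing in dilation radius and
           percent stays within [0, 100]", {
  sp <- network3d_spec(volume_shape_vox = c(100, 100, 80), n_actin = 8,
                       n_mt = 8, paired_fraction = 0.5,
                       pair_offset_nm = 200, length_um_range = c(3, 6),
                       seed = 5)
  net <- gen_network_volume(sp)
  traces <- trace_polymers(net$actin)
  tot <- vapply(1:6, function(r) {
    res <- interaction_map(net$actin, net$mt, r, traces = traces)
    expect_gte(res$percent_interacting, 0)
    expect_lte(res$percent_interacting, 100)
    res$total_interacting_actin_um
  }, numeric(1))
  expect_true(all(diff(tot) >= -1e-9))
})

test_that("total actin length equals the sum of trace lengths exactly", {
  sp <- network3d_spec(volume_shape_vox = c(100, 100, 80), n_actin = 6,
                       n_mt = 3, paired_fraction = 0,
                       length_um_range = c(3, 6), seed = 31)
  net <- gen_network_volume(sp)
  traces <- trace_polymers(net$actin)
  res <- interaction_map(net$actin, net$mt, 4, traces = traces)
  expect_equal(res$total_actin_um, sum(traces$length_um), tolerance = 1e-12)
})

test_that("pitch is unchanged by a 90-degree rotation about z", {
  sp <- network3d_spec(volume_shape_vox = c(80, 80, 80), n_actin = 6,
                       n_mt = 0, length_um_range = c(3, 6), seed = 17)
  net <- gen_network_volume(sp)
  rot <- aperm(net$actin$voxels, c(2, 1, 3))[dim(net$actin$voxels)[2]:1, , ]
  tr0 <- trace_polymers(net$actin)
  tr1 <- trace_polymers(tm_volume(rot, net$actin$voxel_size_nm, "actin"))
  expect_equal(sort(tr0$pitch_deg), sort(tr1$pitch_deg), tolerance = 1e-6)
})

test_that("area_vs_depth recovers constructed slopes and the cylinder null", {
  vs <- c(100, 100, 100)
  nz <- 50
  cellv <- array(FALSE, dim = c(300, 300, nz))
  bundv <- array(FALSE, dim = c(300, 300, nz))
  for (z in seq_len(nz)) {
    depth <- (z - 1) * 0.1
    side <- round(sqrt(20 + 5.412 * depth) * 10)   # cell area in 0.1 um px
    cellv[seq_len(side), seq_len(side), z] <- TRUE
    sideb <- round(sqrt(5 + 2.013 * depth) * 10)
    bundv[seq_len(sideb), seq_len(sideb), z] <- TRUE
  }
  da <- area_vs_depth(tm_volume(cellv, vs, "cell"),
                      tm_volume(bundv, vs, "bundle_region"))
  expect_equal(da$slope_cell, 5.412, tolerance = 0.02)
  expect_equal(da$slope_bundle, 2.013, tolerance = 0.03)

  cyl <- array(FALSE, dim = c(60, 60, 40))
  for (z in 1:40) {
    cyl[, , z] <- outer(1:60, 1:60,
                        function(i, j) (i - 30.5)^2 + (j - 30.5)^2 <= 20^2)
  }
  cyl_vol <- tm_volume(cyl, vs, "cell")
  da0 <- area_vs_depth(cyl_vol, cyl_vol, depths_um = c(0, 1, 2, 3))
  expect_equal(da0$slope_cell, 0, tolerance = 1e-9)

  # single-column bundle: one hull cell per slice, slope ~ 0
  col <- column_volume(list(c(30, 30, 40)), shape = c(60, 60, 40))
  dac <- area_vs_depth(cyl_vol, col, depths_um = c(0, 1, 2))
  expect_equal(unique(dac$table$bundle_area_um2), 0.01)
  expect_equal(dac$slope_bundle, 0, tolerance = 1e-9)

  expect_error(area_vs_depth(cyl_vol, cyl_vol, depths_um = 100), "outside")
})

test_that("apical shape descriptors match closed forms", {
  n <- 120; r <- 50
  disc <- outer(1:n, 1:n,
                function(i, j) (i - 60.5)^2 + (j - 60.5)^2 <= r^2)
  sh <- apical_shape(disc, 0.1)
  expect_equal(sh$area_um2, sum(disc) * 0.01)
  expect_gte(sh$circularity, 0.95)
  expect_lte(sh$circularity, 1.01)

  sq <- matrix(FALSE, 100, 100); sq[26:75, 26:75] <- TRUE
  expect_equal(apical_shape(sq, 0.1)$circularity, pi / 4, tolerance = 0.025)

  bar <- matrix(FALSE, 20, 120); bar[10, 11:110] <- TRUE
  expect_lt(apical_shape(bar, 0.1)$circularity, 0.1)

  expect_error(apical_shape(matrix(FALSE, 10, 10), 0.1), "empty")
  two <- matrix(FALSE, 20, 20); two[2, 2] <- TRUE; two[18, 18] <- TRUE
  expect_error(apical_shape(two, 0.1), "2")
})
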