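# Packing statistics: detection, neighbour graph, triplet angles, summary.

test_that("detect_centers finds a single rendered blob within half a pixel", {
  pts <- tibble::tibble(id = 1L, x_nm = 24.3, y_nm = 31.7)
  img <- render_cross_section(pts, render_spec(pixel_size_nm = 1,
                                               psf_sigma_nm = 2,
                                               image_shape_px = c(64, 64)))
  det <- detect_centers(img, expected_spacing_nm = 9)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x_nm - 24.3)^2 + (det$y_nm - 31.7)^2), 0.5)
})

test_that("a flat image yields zero detections with a warning, not an error", {
  img <- tm_image(matrix(0.5, 40, 40), 1)
  expect_warning(det <- detect_centers(img, 9), "flat")
  expect_equal(nrow(det), 0)
})

test_that("all 7 rosette blobs are detected within a quarter spacing", {
  fix <- rosette_image(d = 9, psf = 2, px = 1, noise_sd = 0.005)
  det <- detect_centers(fix$image, expected_spacing_nm = 9)
  expect_equal(nrow(det), 7)
  for (k in seq_len(7)) {
    err <- min(sqrt((fix$points$x_nm - det$x_nm[k])^2 +
                      (fix$points$y_nm - det$y_nm[k])^2))
    expect_lt(err, 9 / 4)
  }
})

test_that("neighbour graph handles singletons, pairs and the rosette", {
  one <- tibble::tibble(id = 1L, x_nm = 0, y_nm = 0)
  g1 <- build_neighbor_graph(one, 12)
  expect_equal(nrow(g1), 0)
  s1 <- summarize_packing(one, g1)
  expect_equal(s1$nn_count_histogram[[1]],
               tibble::tibble(degree = 0L, count = 1L))

  two <- tibble::tibble(id = 1:2, x_nm = c(0, 9), y_nm = c(0, 0))
  g2 <- build_neighbor_graph(two, 12)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$distance_nm, 9)

  ros <- rosette_points(9)
  g <- build_neighbor_graph(ros, 12)
  deg <- table(c(g$i, g$j))
  expect_equal(sort(as.integer(deg)), c(rep(3L, 6), 6L))
  # ring-ring second neighbours at 9 * sqrt(3) ~ 15.6 nm are excluded
  expect_true(all(g$distance_nm <= 12))
})

test_that("graph and angles match the brute-force reference exactly", {
  for (sd in 1:5) {
    pts <- gen_lattice_points(lattice_spec("csr", n_points = 60,
                                           bundle_radius_nm = 30, seed = sd))
    g <- build_neighbor_graph(pts, 12)
    ref <- brute_graph(pts, 12)
    expect_equal(dplyr::arrange(as.data.frame(g), i, j),
                 dplyr::arrange(as.data.frame(ref), i, j),
                 tolerance = 1e-12, ignore_attr = TRUE)
    a <- triplet_angles(pts, g)
    ref_a <- brute_angles(pts, ref)
    expect_equal(sort(a$angle_deg), sort(ref_a$angle_deg),
                 tolerance = 1e-9)
  }
})

test_that("triplet angles reproduce exact lattice geometry", {
  ros <- rosette_points(9)
  g <- build_neighbor_graph(ros, 12)
  a <- triplet_angles(ros, g)
  expect_equal(sort(a$angle_deg[a$focal_id == 1]), rep(60, 6),
               tolerance = 1e-9)

  # interior point of a 3x3 square patch: four angles of 90 degrees
  sq <- tidyr::expand_grid(gx = 0:2, gy = 0:2)
  sq <- tibble::tibble(id = 1:9, x_nm = sq$gx * 9, y_nm = sq$gy * 9)
  gs <- build_neighbor_graph(sq, 12)
  centre_id <- sq$id[sq$x_nm == 9 & sq$y_nm == 9]
  as <- triplet_angles(sq, gs)
  expect_equal(sort(as$angle_deg[as$focal_id == centre_id]), rep(90, 4),
               tolerance = 1e-9)

  # collinear triple, focal point of degree 2: one angle of 180
  tri <- tibble::tibble(id = 1:3, x_nm = c(0, 9, 18), y_nm = 0)
  gt <- build_neighbor_graph(tri, 12)
  at <- triplet_angles(tri, gt)
  expect_equal(at$angle_deg[at$focal_id == 2], 180, tolerance = 1e-9)
})

test_that("rosette summary: spacing 9, diameter 27, median angle 60", {
  ros <- rosette_points(9)
  s <- summarize_packing(ros, build_neighbor_graph(ros, 12))
  expect_equal(s$n_points, 7)
  expect_equal(s$estimated_spacing_nm, 9, tolerance = 1e-12)
  expect_equal(s$median_triplet_angle_deg, 60, tolerance = 1e-9)
  # min enclosing circle of the hexagon = circumscribed circle (diameter 2d),
  # plus one spacing for filament extent
  expect_equal(s$bundle_diameter_nm, 27, tolerance = 1e-9)
})

test_that("three far-apart points give an empty graph and no angles", {
  far <- tibble::tibble(id = 1:3, x_nm = c(0, 100, 200), y_nm = 0)
  g <- build_neighbor_graph(far, 12)
  s <- summarize_packing(far, g)
  expect_equal(s$nn_count_histogram[[1]],
               tibble::tibble(degree = 0L, count = 3L))
  expect_length(s$triplet_angles_deg[[1]], 0)
  # spacing falls back to the unbounded nearest neighbour
  expect_equal(s$estimated_spacing_nm, 100)
})

test_that("packing summaries are invariant under rigid motions", {
  pts <- gen_lattice_points(lattice_spec("hex", spacing_nm = 9,
                                         jitter_sd_nm = 0.3,
                                         bundle_radius_nm = 30, seed = 3))
  th <- 27 * pi / 180
  rot <- tibble::tibble(
    id = pts$id,
    x_nm = cos(th) * pts$x_nm - sin(th) * pts$y_nm + 111,
    y_nm = sin(th) * pts$x_nm + cos(th) * pts$y_nm - 55)
  s0 <- glance(summarize_packing(pts, build_neighbor_graph(pts, 12)))
  s1 <- glance(summarize_packing(rot, build_neighbor_graph(rot, 12)))
  expect_equal(as.data.frame(s0), as.data.frame(s1), tolerance = 1e-9)
})

test_that("triplet-angle disorder grows with jitter", {
  dev_at <- function(jit) {
    devs <- vapply(1:8, function(sd) {
      p <- gen_lattice_points(lattice_spec("hex", spacing_nm = 9,
                                           jitter_sd_nm = jit,
                                           bundle_radius_nm = 40,
                                           seed = sd))
      a <- triplet_angles(p, build_neighbor_graph(p, 12))
      median(abs(a$angle_deg - 60))
    }, numeric(1))
    median(devs)
  }
  devs <- vapply(c(0, 0.45, 1.35, 2.7), dev_at, numeric(1))
  expect_true(all(diff(devs) >= 0))
})

test_that("hex degree histogram modes at 6; matched-density csr modes lower", {
  hexp <- gen_lattice_points(lattice_spec("hex", spacing_nm = 9,
                                          bundle_radius_nm = 50, seed = 2))
  n_csr <- nrow(hexp)  # same density on the same disc
  csrp <- gen_lattice_points(lattice_spec("csr", n_points = n_csr,
                                          bundle_radius_nm = 50, seed = 2))
  modal <- function(p) {
    h <- summarize_packing(p, build_neighbor_graph(p, 12))$
      nn_count_histogram[[1]]
    h$degree[which.max(h$count)]
  }
  expect_equal(modal(hexp), 6L)
  expect_lt(modal(csrp), 6L)
})

test_that("minimum enclosing circle is exact on known configurations", {
  expect_equal(unname(min_enclosing_circle(cbind(c(0, 2), c(0, 0)))),
               c(1, 0, 1))
  ros <- rosette_points(9, centre = c(5, 7))
  mec <- min_enclosing_circle(cbind(ros$x_nm, ros$y_nm))
  expect_equal(unname(mec), c(5, 7, 9), tolerance = 1e-9)
  # random clouds: all points inside, circle supported by >= 2 points
  for (sd in 1:5) {
    pts <- gen_lattice_points(lattice_spec("csr", n_points = 40,
                                           bundle_radius_nm = 20, seed = sd))
    mec <- min_enclosing_circle(cbind(pts$x_nm, pts$y_nm))
    r_all <- sqrt((pts$x_nm - mec["x"])^2 + (pts$y_nm - mec["y"])^2)
    expect_lte(max(r_all), mec["radius"] * (1 + 1e-9))
    expect_gte(sum(abs(r_all - mec["radius"]) < 1e-6 * mec["radius"]), 2)
  }
})
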