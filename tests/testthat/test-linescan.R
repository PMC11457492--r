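# Profile generation, extraction, normalisation and model fitting.

test_that("profile generator honours its models at noise zero", {
  const <- gen_profile(profile_spec("constant", params = 0.4,
                                    n_samples = 20))
  expect_true(all(const$intensity == 0.4))

  # 4PL with the bottom plateau at the tip: value at x = 0 equals bottom
  fp <- gen_profile(profile_spec("four_pl", params = c(0.15, 0.66, 3, 4),
                                 axis_length_um = 7, n_samples = 100))
  expect_equal(fp$intensity[1], 0.15, tolerance = 1e-6)
  # analytic value at the far end (the sigmoid has not fully plateaued)
  expect_equal(fp$intensity[100], 0.66 + (0.15 - 0.66) / (1 + (7 / 3)^4),
               tolerance = 1e-9)

  # lognormal: sample argmax falls on the grid point nearest the mode
  ln <- gen_profile(profile_spec("lognormal", params = c(1, 2.5, 0.6),
                                 axis_length_um = 7, n_samples = 100))
  grid <- ln$arclength_um
  expect_equal(which.max(ln$intensity), which.min(abs(grid - 2.5)))

  expect_error(profile_spec("lognormal", params = c(1, 2)), "3 parameters")
  expect_error(profile_spec("constant", params = 1, n_samples = 4),
               "at least 8")
})

test_that("profile generation is deterministic in spec + seed", {
  sp <- profile_spec("lognormal", params = c(1, 2, 0.5), noise_sd = 0.1,
                     seed = 7)
  expect_identical(gen_profile(sp), gen_profile(sp))
})

test_that("extract_profile reproduces constant and ramp closed forms", {
  flat <- tm_image(matrix(0.6, 40, 40), 2)
  pr <- extract_profile(flat, rbind(c(10, 40), c(70, 40)), width_px = 10)
  expect_true(all(abs(pr$intensity - 0.6) < 1e-12))

  # vertical linear ramp, horizontal scan line: perpendicular averaging is
  # symmetric, so the profile is constant at the centre-row value
  ramp <- tm_image(matrix(rep(1:40, 40), 40, 40), 2)
  pr2 <- extract_profile(ramp, rbind(c(12, 40), c(68, 40)), width_px = 9)
  expect_lt(diff(range(pr2$intensity)), 1e-9)
  # scan at y = 40 nm sits midway between the row centres valued 20 and 21
  expect_equal(pr2$intensity[1], 20.5, tolerance = 1e-9)

  expect_error(extract_profile(flat, rbind(c(10, 40), c(500, 40))),
               "bounds")
})

test_that("profile along a Gaussian stripe peaks at the stripe centre", {
  n <- 60
  stripe <- tm_image(matrix(rep(exp(-((1:n) - 30.2)^2 / (2 * 3^2)), n),
                            n, n, byrow = TRUE), 1)
  # scan across columns (x varies) along the stripe's gradient
  pr <- extract_profile(stripe, rbind(c(5, 30), c(55, 30)), width_px = 5)
  peak_x <- pr$arclength_um[which.max(pr$intensity)] * 1000 + 5
  expect_lt(abs(peak_x - 29.7), 1.01)  # within one sample of the centre
})

test_that("normalisation maps any profile onto [0, 1] and flags it", {
  pr <- tibble::tibble(arclength_um = 0:2, intensity = c(2, 4, 6))
  np <- normalize_profile(pr)
  expect_equal(np$intensity, c(0, 0.5, 1))
  expect_true(attr(np, "normalized"))
  expect_identical(normalize_profile(np)$intensity, np$intensity)
  expect_error(normalize_profile(tibble::tibble(arclength_um = 0:2,
                                                intensity = rep(1, 3))),
               "constant")
})

test_that("noiseless fits recover generator parameters to 1e-3 relative", {
  cases <- list(
    list(model = "lognormal", params = c(1, 2.5, 0.6)),
    list(model = "four_pl", params = c(0.15, 0.66, 3, 4)),
    list(model = "exp_decay", params = c(0.8, 2, 0.1)))
  for (cs in cases) {
    pr <- gen_profile(profile_spec(cs$model, params = cs$params,
                                   axis_length_um = 7, n_samples = 100))
    fit <- fit_profile(pr, cs$model)
    expect_true(fit$converged)
    expect_equal(unname(fit$params), cs$params, tolerance = 1e-3)
  }
  # lognormal peak is the analytic mode; 4PL plateaus are reported
  ln <- fit_profile(gen_profile(profile_spec("lognormal",
                                             params = c(1, 2.5, 0.6),
                                             axis_length_um = 7,
                                             n_samples = 100)), "lognormal")
  expect_equal(ln$peak_position_um, 2.5, tolerance = 1e-3)
  fp <- fit_profile(gen_profile(profile_spec("four_pl",
                                             params = c(0.15, 0.66, 3, 4),
                                             axis_length_um = 7,
                                             n_samples = 100)), "four_pl")
  expect_equal(unname(fp$plateaus), c(0.15, 0.66), tolerance = 1e-3)
})

test_that("quartic fit on exact quartic samples is machine precision", {
  pr <- gen_profile(profile_spec("quartic",
                                 params = c(0.2, 0.5, -0.2, 0.02, -8e-4),
                                 axis_length_um = 7, n_samples = 60))
  fit <- fit_profile(pr, "quartic")
  expect_lte(fit$rss, 1e-10)
  expect_true(fit$converged)
  # peak = argmax of the fitted polynomial within the span
  curve <- tuftmorph:::profile_model_fun("quartic")
  xs <- seq(0, 7, length.out = 2000)
  expect_equal(fit$peak_position_um,
               xs[which.max(curve(xs, unname(fit$params)))],
               tolerance = 0.01)
})

test_that("fits survive heavy noise without exceptions and report rss no
           worse than the initialisation", {
  pr <- gen_profile(profile_spec("lognormal", params = c(1, 2.5, 0.6),
                                 axis_length_um = 7, n_samples = 50,
                                 noise_sd = 0.5, seed = 3))
  fit <- fit_profile(pr, "lognormal")
  init <- tuftmorph:::fit_init(pr$arclength_um, pr$intensity, "lognormal")
  half <- diff(pr$arclength_um[1:2]) / 2
  xs <- ifelse(pr$arclength_um <= 0, half, pr$arclength_um)
  rss_init <- sum((pr$intensity -
                     tuftmorph:::profile_model_fun("lognormal")(xs, init))^2)
  expect_lte(fit$rss, rss_init + 1e-12)
})

test_that("intensity scaling scales amplitudes and plateaus, not peaks", {
  pr <- gen_profile(profile_spec("lognormal", params = c(1, 2.5, 0.6),
                                 axis_length_um = 7, n_samples = 100,
                                 noise_sd = 0.05, seed = 9))
  f1 <- fit_profile(pr, "lognormal")
  pr3 <- dplyr::mutate(pr, intensity = intensity * 3)
  f3 <- fit_profile(pr3, "lognormal")
  expect_equal(f3$params[["amplitude"]], 3 * f1$params[["amplitude"]],
               tolerance = 1e-6)
  expect_equal(f3$peak_position_um, f1$peak_position_um, tolerance = 1e-6)
})

test_that("peak-position error shrinks as noise drops", {
  err_at <- function(noise) {
    errs <- vapply(1:25, function(sd) {
      pr <- gen_profile(profile_spec("lognormal", params = c(1, 2.5, 0.6),
                                     axis_length_um = 7, n_samples = 60,
                                     noise_sd = noise, seed = sd))
      abs(fit_profile(pr, "lognormal")$peak_position_um - 2.5)
    }, numeric(1))
    median(errs)
  }
  errs <- vapply(c(0.3, 0.1, 0.03), err_at, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("pooled fitting matches single-profile fits and keeps its grid
           contract", {
  pr <- gen_profile(profile_spec("lognormal", params = c(1, 2.5, 0.6),
                                 axis_length_um = 7, n_samples = 80))
  ag <- aggregate_profiles(list(pr, pr), "lognormal")
  # pooling two identical profiles duplicates the resampled points, so the
  # pooled fit equals the fit through one resampled copy
  single <- fit_profile(
    tibble::tibble(arclength_um = ag$mean_curve$frac,
                   intensity = ag$mean_curve$mean_intensity), "lognormal")
  expect_equal(unname(ag$fit$params), unname(single$params),
               tolerance = 1e-9)
  expect_equal(nrow(ag$mean_curve), 100)
  expect_equal(range(ag$mean_curve$frac), c(0, 1))

  # different raw lengths still land on the common fractional grid
  pr2 <- gen_profile(profile_spec("lognormal", params = c(1, 1.2, 0.6),
                                  axis_length_um = 3.3, n_samples = 40))
  ag2 <- aggregate_profiles(list(pr, pr2), "lognormal")
  expect_equal(nrow(ag2$mean_curve), 100)

  # 30 noisy lognormal profiles: pooled peak within 5% of the true mode
  profs <- lapply(1:30, function(sd) {
    gen_profile(profile_spec("lognormal", params = c(1, 2.5, 0.6),
                             axis_length_um = 7, n_samples = 100,
                             noise_sd = 0.1, seed = sd))
  })
  ag3 <- aggregate_profiles(profs, "lognormal")
  expect_equal(ag3$fit$peak_position_um, 2.5 / 7, tolerance = 0.05)
})

test_that("tidy and glance expose fit results broom-style", {
  fit <- fit_profile(gen_profile(profile_spec("four_pl",
                                              params = c(0.15, 0.66, 3, 4),
                                              n_samples = 50)), "four_pl")
  td <- generics::tidy(fit)
  expect_equal(td$term, c("bottom", "top", "midpoint_um", "hill"))
  gl <- generics::glance(fit)
  expect_equal(gl$bottom, 0.15, tolerance = 1e-3)
  expect_true(gl$converged)
})
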