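## Arclength intensity profiles and regionalization model fitting.

#' Extract an intensity profile along a polyline
#'
#' Samples the image by bilinear interpolation at unit-pixel arclength steps
#' along the polyline, averaging `width_px` samples taken perpendicular to
#' the local direction (the linescan "thickness"). Arclength is reported in
#' um with the first vertex (the bundle tip) at 0.
#'
#' @param image A [tm_image()].
#' @param polyline_nm Two-column matrix of ordered `(x, y)` vertices in nm,
#'   at least two.
#' @param width_px Number of perpendicular samples averaged per step
#'   (default 10).
#' @return A tibble with `arclength_um`, `intensity`; attributes `width_px`
#'   and `normalized = FALSE`.
#' @export
extract_profile <- function(image, polyline_nm, width_px = 10L) {
  stopifnot(inherits(image, "tm_image"))
  polyline_nm <- as.matrix(polyline_nm)
  if (nrow(polyline_nm) < 2) abort("polyline needs at least 2 vertices")
  px <- image$pixel_size_nm
  v <- polyline_nm / px  # continuous pixel units
  w_img <- ncol(image$pixels); h_img <- nrow(image$pixels)
  if (any(v[, 1] < 0 | v[, 1] > w_img | v[, 2] < 0 | v[, 2] > h_img)) {
    abort("polyline exits the image bounds")
  }
  seglen <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = 1)
  if (s[length(s)] < total) s <- c(s, total)
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg[seg >= nrow(polyline_nm)] <- nrow(polyline_nm) - 1L
  t0 <- (s - cum[seg]) / seglen[seg]
  xs <- v[seg, 1] + t0 * (v[seg + 1, 1] - v[seg, 1])
  ys <- v[seg, 2] + t0 * (v[seg + 1, 2] - v[seg, 2])
  dx <- (v[seg + 1, 1] - v[seg, 1]) / seglen[seg]
  dy <- (v[seg + 1, 2] - v[seg, 2]) / seglen[seg]
  offs <- seq_len(width_px) - (width_px + 1) / 2
  acc <- matrix(NA_real_, length(s), width_px)
  for (k in seq_along(offs)) {
    acc[, k] <- interp_bilinear(image$pixels,
                                xs - offs[k] * dy, ys + offs[k] * dx)
  }
  inten <- rowMeans(acc, na.rm = TRUE)
  if (any(is.nan(inten))) abort("profile sample entirely outside the image")
  out <- tibble(arclength_um = s * px / 1000, intensity = inten)
  attr(out, "width_px") <- as.integer(width_px)
  attr(out, "normalized") <- FALSE
  out
}

#' Normalise a profile's intensities to the unit interval
#'
#' `(I - min) / (max - min)`, as used for per-profile normalised intensity.
#'
#' @param profile Tibble with `arclength_um`, `intensity`.
#' @return The profile with intensities in `[0, 1]` and attribute
#'   `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  rng <- range(profile$intensity)
  if (diff(rng) <= 0) abort("cannot normalise a constant profile")
  out <- dplyr::mutate(profile,
                       intensity = (.data$intensity - rng[1]) / diff(rng))
  attr(out, "width_px") <- attr(profile, "width_px")
  attr(out, "normalized") <- TRUE
  out
}

## --- fitting ---------------------------------------------------------------

rss_of <- function(x, y, model, p) sum((y - profile_model_fun(model)(x, p))^2)

# Documented initial parameter estimates per model.
fit_init <- function(x, y, model) {
  switch(model,
    lognormal = {
      m0 <- x[which.max(y)]
      if (m0 <= 0) m0 <- x[x > 0][1]
      c(max(y), m0, 0.5)
    },
    four_pl = {
      k <- max(3L, ceiling(length(y) / 10))
      bottom <- mean(head(y, k)); top <- mean(tail(y, k))
      half <- (bottom + top) / 2
      cross <- which(((y - half) * (bottom - half)) < 0)[1]
      mid <- if (!is.na(cross)) x[cross] else median(x)
      if (!is.finite(mid) || mid <= 0) mid <- median(x[x > 0])
      c(bottom, top, mid, 1)
    },
    exp_decay = {
      off <- min(y)
      amp <- max(y[1] - off, 1e-6)
      pos <- y - off > amp * 0.05 & x > 0
      lam <- if (sum(pos) > 2) {
        fitl <- lm(log(y[pos] - off + 1e-12) ~ x[pos])
        max(-1 / coef(fitl)[2], diff(range(x)) / 20)
      } else diff(range(x)) / 3
      c(amp, unname(lam), off)
    },
    abort(sprintf("no nonlinear initialisation for model '%s'", model))
  )
}

fit_one_start <- function(x, y, model, start) {
  f <- profile_model_fun(model)
  nm <- paste0("p", seq_along(start))
  names(start) <- nm
  form <- switch(model,
    lognormal = y ~ p1 * exp(-(log(xs / p2))^2 / (2 * p3^2)),
    four_pl = y ~ p2 + (p1 - p2) / (1 + (x / p3)^p4),
    exp_decay = y ~ p1 * exp(-x / p2) + p3)
  # nudge nonpositive arclengths by half a sample so ln(0) cannot occur
  half <- if (length(x) > 1) diff(x[1:2]) / 2 else 0.5
  dat <- data.frame(x = x, xs = ifelse(x <= 0, half, x), y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- unname(coef(fit))
  xeval <- if (model == "lognormal") dat$xs else dat$x
  list(params = p, rss = rss_of(xeval, y, model, p))
}

#' Fit a regionalization model to an intensity profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a documented
#' initialisation and five multi-starts (the documented start plus four
#' jittered copies under a fixed internal RNG); the lowest-RSS fit wins and
#' never exceeds the RSS of the initialisation itself. The quartic model is
#' solved in closed form by linear least squares. Lognormal arclengths at 0
#' are nudged by half a sample so the log is defined.
#'
#' @param profile Tibble with `arclength_um`, `intensity` (>= number of
#'   parameters + 3 samples).
#' @param model `"lognormal"`, `"four_pl"`, `"quartic"` or `"exp_decay"`.
#' @param n_starts Number of multi-starts for the nonlinear models.
#' @return An object of class `tm_fit`: list with `model`, `params`,
#'   `peak_position_um` (lognormal mode / quartic argmax, otherwise `NA`),
#'   `plateaus` (named bottom/top for `four_pl`, otherwise `NULL`), `rss`,
#'   `converged`, and the fitted `data`. Non-convergence yields
#'   `converged = FALSE` with best-effort parameters, never an error.
#' @export
fit_profile <- function(profile,
                        model = c("lognormal", "four_pl", "quartic",
                                  "exp_decay"),
                        n_starts = 5L) {
  model <- match.arg(model)
  x <- profile$arclength_um; y <- profile$intensity
  need <- profile_model_arity[[model]] + 3L
  if (length(x) < need) {
    abort(sprintf("model '%s' needs at least %d samples, got %d",
                  model, need, length(x)))
  }
  if (model == "quartic") {
    fitl <- lm(y ~ x + I(x^2) + I(x^3) + I(x^4))
    p <- unname(coef(fitl))
    peak <- optimize(function(t) profile_model_fun("quartic")(t, p),
                     range(x), maximum = TRUE)$maximum
    return(new_tm_fit(model, p, peak, NULL, sum(resid(fitl)^2), TRUE,
                      profile))
  }
  init <- fit_init(x, y, model)
  starts <- with_seed(4242L, {
    c(list(init), purrr::map(seq_len(max(0L, n_starts - 1L)), function(i) {
      init * runif(length(init), 0.8, 1.2)
    }))
  })
  cands <- purrr::compact(purrr::map(starts, ~fit_one_start(x, y, model, .x)))
  half <- if (length(x) > 1) diff(x[1:2]) / 2 else 0.5
  xs <- if (model == "lognormal") ifelse(x <= 0, half, x) else x
  init_cand <- list(params = init, rss = rss_of(xs, y, model, init))
  if (!length(cands)) {
    best <- init_cand; converged <- FALSE
  } else {
    best <- cands[[which.min(purrr::map_dbl(cands, "rss"))]]
    converged <- TRUE
    if (best$rss > init_cand$rss) { best <- init_cand; converged <- FALSE }
  }
  if (model == "four_pl" && best$params[4] < 0) {
    # (bottom, top, hill) <-> (top, bottom, -hill) is an exact symmetry of
    # the logistic; canonicalise to a positive hill slope so "bottom" is
    # always the x = 0 plateau
    best$params <- c(best$params[2], best$params[1], best$params[3],
                     -best$params[4])
  }
  peak <- switch(model, lognormal = best$params[2], NA_real_)
  plateaus <- if (model == "four_pl") {
    c(bottom = best$params[1], top = best$params[2])
  }
  new_tm_fit(model, best$params, peak, plateaus, best$rss, converged, profile)
}

new_tm_fit <- function(model, params, peak, plateaus, rss, converged, data) {
  names(params) <- switch(model,
    lognormal = c("amplitude", "mode_um", "shape"),
    four_pl = c("bottom", "top", "midpoint_um", "hill"),
    quartic = paste0("c", 0:4),
    exp_decay = c("amplitude", "decay_um", "offset"))
  structure(list(model = model, params = params,
                 peak_position_um = peak, plateaus = plateaus,
                 rss = rss, converged = converged, data = data),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> %s (%s), rss %.4g\n", x$model,
              if (x$converged) "converged" else "not converged", x$rss))
  print(round(x$params, 5))
  if (!is.na(x$peak_position_um)) {
    cat(sprintf("peak at %.4g um\n", x$peak_position_um))
  }
  invisible(x)
}

# Evaluate a tm_fit at new arclengths.
predict_tm_fit <- function(fit, x) {
  half <- {
    xx <- fit$data$arclength_um
    if (length(xx) > 1) diff(xx[1:2]) / 2 else 0.5
  }
  xs <- if (fit$model == "lognormal") ifelse(x <= 0, half, x) else x
  profile_model_fun(fit$model)(xs, unname(fit$params))
}

#' Pool and fit a set of profiles
#'
#' Resamples every profile to a common fractional arclength grid (100 points
#' on `[0, 1]`), pools the resampled points, and fits the model once through
#' the pooled cloud (mirroring a single fit drawn through all raw traces),
#' alongside per-profile fits.
#'
#' @param profiles List of profile tibbles (>= 2, each with positive length).
#' @param model Model name passed to [fit_profile()].
#' @param grid_n Number of fractional grid points.
#' @return A list of class `tm_profile_pool` with `mean_curve` (tibble
#'   `frac`, `mean_intensity`), `pooled` (tibble `frac`, `intensity`,
#'   `profile`), `fit` (pooled `tm_fit`, arclength in fractional units) and
#'   `per_profile` (list of `tm_fit`).
#' @export
aggregate_profiles <- function(profiles, model, grid_n = 100L) {
  if (length(profiles) < 2) abort("need at least 2 profiles")
  grid <- seq(0, 1, length.out = grid_n)
  res <- purrr::imap(profiles, function(p, i) {
    span <- max(p$arclength_um)
    if (span <= 0) abort(sprintf("profile %s has zero length", i))
    tibble(frac = grid,
           intensity = approx(p$arclength_um / span, p$intensity,
                              xout = grid, rule = 2)$y,
           profile = as.character(i))
  })
  pooled <- dplyr::bind_rows(res)
  mean_curve <- pooled |>
    dplyr::group_by(.data$frac) |>
    dplyr::summarise(mean_intensity = mean(.data$intensity))
  pool_profile <- tibble(arclength_um = pooled$frac,
                         intensity = pooled$intensity)
  fit <- fit_profile(pool_profile, model)
  per <- purrr::map(profiles, function(p) fit_profile(p, model))
  structure(list(mean_curve = mean_curve, pooled = pooled, fit = fit,
                 per_profile = per),
            class = "tm_profile_pool")
}
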