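## Intensity-profile models shared by the generator and the fitter.
##
## lognormal:  A * exp(-(ln(x/m))^2 / (2 s^2)),   0 at x <= 0 (by limit)
## four_pl:    top + (bottom - top) / (1 + (x/mid)^hill)   (bottom at x = 0)
## quartic:    c0 + c1 x + c2 x^2 + c3 x^3 + c4 x^4
## exp_decay:  A * exp(-x / lambda) + offset
## constant:   c

profile_model_fun <- function(model) {
  switch(model,
    lognormal = function(x, p) {
      out <- numeric(length(x))
      pos <- x > 0
      out[pos] <- p[1] * exp(-(log(x[pos] / p[2]))^2 / (2 * p[3]^2))
      out
    },
    four_pl = function(x, p) {
      p[2] + (p[1] - p[2]) / (1 + (x / p[3])^p[4])
    },
    quartic = function(x, p) {
      p[1] + p[2] * x + p[3] * x^2 + p[4] * x^3 + p[5] * x^4
    },
    exp_decay = function(x, p) p[1] * exp(-x / p[2]) + p[3],
    constant = function(x, p) rep(p[1], length(x)),
    abort(sprintf("unknown profile model '%s'", model))
  )
}

profile_model_arity <- c(lognormal = 3L, four_pl = 4L, quartic = 5L,
                         exp_decay = 3L, constant = 1L)

#' Specification of a synthetic intensity linescan
#'
#' @param model One of `"lognormal"` (amplitude, mode position um, shape),
#'   `"four_pl"` (bottom, top, midpoint um, hill), `"quartic"` (5
#'   coefficients), `"exp_decay"` (amplitude, decay length um, offset),
#'   `"constant"` (level).
#' @param params Numeric parameter vector of the model's arity.
#' @param axis_length_um Profile length; samples are equally spaced on
#'   `[0, axis_length_um]`.
#' @param n_samples Number of samples (>= 8).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list of class `profile_spec`.
#' @export
profile_spec <- function(model = c("lognormal", "four_pl", "quartic",
                                   "exp_decay", "constant"),
                         params,
                         axis_length_um = 7,
                         n_samples = 100L,
                         noise_sd = 0,
                         seed = 1L) {
  model <- match.arg(model)
  if (length(params) != profile_model_arity[[model]]) {
    abort(sprintf("model '%s' takes %d parameters, got %d.",
                  model, profile_model_arity[[model]], length(params)))
  }
  if (n_samples < 8) abort("`n_samples` must be at least 8.")
  assert_scalar_pos(axis_length_um, "axis_length_um")
  assert_scalar_nonneg(noise_sd, "noise_sd")
  structure(list(model = model, params = as.numeric(params),
                 axis_length_um = axis_length_um,
                 n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "profile_spec")
}

#' Generate a synthetic intensity linescan
#'
#' Evaluates the model on `n_samples` equally spaced arclengths covering
#' `[0, axis_length_um]` (tip at 0, base at the end) and adds Gaussian noise.
#'
#' @param spec A [profile_spec()].
#' @return A tibble with columns `arclength_um` and `intensity`; the spec is
#'   attached as attribute `spec`.
#' @export
gen_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  x <- seq(0, spec$axis_length_um, length.out = spec$n_samples)
  f <- profile_model_fun(spec$model)
  y <- f(x, spec$params)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(spec$seed, rnorm(length(x), 0, spec$noise_sd))
  }
  out <- tibble(arclength_um = x, intensity = y)
  attr(out, "spec") <- spec
  out
}
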