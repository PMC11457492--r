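#' Specification of a synthetic filament-lattice cross-section
#'
#' Describes the point process used to generate filament centres inside a
#' circular bundle cross-section. `"hex"` gives a triangular (hexagonally
#' packed) lattice, `"square"` a square lattice, and `"csr"` complete spatial
#' randomness (a binomial point process on the disc) as the disorder control.
#'
#' @param lattice_kind One of `"hex"`, `"square"`, `"csr"`.
#' @param spacing_nm Nearest-neighbour centre-to-centre distance d in nm
#'   (ignored for `"csr"`). Tuft-cell core bundles show d close to 9.2 nm.
#' @param jitter_sd_nm SD of isotropic Gaussian positional jitter applied to
#'   every lattice point (per axis), nm.
#' @param vacancy_fraction Probability in `[0, 1)` that a lattice point is
#'   removed, emulating isolated packing dislocations.
#' @param bundle_radius_nm Radius of the disc that clips the lattice; filament
#'   centres all lie within this radius of the bundle centre.
#' @param n_points For `"csr"` only: number of points drawn uniformly on the
#'   disc.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bit-identical point sets.
#' @return A list of class `lattice_spec`.
#' @export
lattice_spec <- function(lattice_kind = c("hex", "square", "csr"),
                         spacing_nm = 9.2,
                         jitter_sd_nm = 0,
                         vacancy_fraction = 0,
                         bundle_radius_nm = 48.45,
                         n_points = NULL,
                         seed = 1L) {
  lattice_kind <- match.arg(lattice_kind)
  if (lattice_kind == "csr") {
    if (is.null(n_points)) abort("csr lattices need `n_points`.")
    assert_scalar_pos(n_points, "n_points")
  } else {
    assert_scalar_pos(spacing_nm, "spacing_nm")
  }
  assert_scalar_nonneg(jitter_sd_nm, "jitter_sd_nm")
  if (!is.numeric(vacancy_fraction) || vacancy_fraction < 0 ||
      vacancy_fraction >= 1) {
    abort("`vacancy_fraction` must lie in [0, 1).")
  }
  assert_scalar_pos(bundle_radius_nm, "bundle_radius_nm")
  structure(list(lattice_kind = lattice_kind, spacing_nm = spacing_nm,
                 jitter_sd_nm = jitter_sd_nm,
                 vacancy_fraction = vacancy_fraction,
                 bundle_radius_nm = bundle_radius_nm,
                 n_points = n_points, seed = as.integer(seed)),
            class = "lattice_spec")
}

# Ideal lattice sites within `radius` of a site at the origin.
lattice_sites <- function(kind, spacing, radius) {
  m <- ceiling(radius / spacing) + 2L
  if (kind == "hex") {
    ij <- expand.grid(i = seq(-2L * m, 2L * m), j = seq(-m, m))
    x <- ij$i * spacing + ij$j * spacing / 2
    y <- ij$j * spacing * sqrt(3) / 2
  } else {
    ij <- expand.grid(i = seq(-m, m), j = seq(-m, m))
    x <- ij$i * spacing
    y <- ij$j * spacing
  }
  keep <- x^2 + y^2 <= radius^2 + 1e-9
  cbind(x = x[keep], y = y[keep])
}

#' Generate filament centres for a synthetic bundle cross-section
#'
#' Places lattice sites (or uniform random points for CSR), clips them to the
#' bundle disc, applies Gaussian jitter and independent vacancies, and centres
#' the bundle at `centre_nm`. The clipping disc is defined on the *ideal*
#' sites, so jitter cannot create or destroy membership.
#'
#' @param spec A [lattice_spec()].
#' @param centre_nm Length-2 bundle centre `(x, y)` in nm. The default places
#'   the bundle so the whole disc has positive coordinates.
#' @return A tibble with columns `id`, `x_nm`, `y_nm` plus attributes
#'   `truth` (the same tibble before jitter/vacancies are unknown: ideal site
#'   positions of the surviving points) and `spec`.
#' @examples
#' pts <- gen_lattice_points(lattice_spec("hex", spacing_nm = 9,
#'                                        bundle_radius_nm = 10))
#' nrow(pts)  # 7: central site plus its six-ring
#' @export
gen_lattice_points <- function(spec, centre_nm = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (is.null(centre_nm)) {
    centre_nm <- rep(spec$bundle_radius_nm + 4 * spec$jitter_sd_nm + 1, 2)
  }
  pts <- with_seed(spec$seed, {
    if (spec$lattice_kind == "csr") {
      n <- as.integer(spec$n_points)
      r <- spec$bundle_radius_nm * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      ideal <- cbind(x = r * cos(th), y = r * sin(th))
      jit <- ideal
    } else {
      ideal <- lattice_sites(spec$lattice_kind, spec$spacing_nm,
                             spec$bundle_radius_nm)
      jit <- ideal
      if (spec$jitter_sd_nm > 0) {
        jit <- ideal + matrix(rnorm(length(ideal), 0, spec$jitter_sd_nm),
                              ncol = 2)
      }
      if (spec$vacancy_fraction > 0) {
        keep <- runif(nrow(ideal)) >= spec$vacancy_fraction
        ideal <- ideal[keep, , drop = FALSE]
        jit <- jit[keep, , drop = FALSE]
      }
    }
    list(ideal = ideal, jit = jit)
  })
  out <- tibble(id = seq_len(nrow(pts$jit)),
                x_nm = pts$jit[, 1] + centre_nm[1],
                y_nm = pts$jit[, 2] + centre_nm[2])
  attr(out, "truth") <- tibble(id = out$id,
                               x_nm = pts$ideal[, 1] + centre_nm[1],
                               y_nm = pts$ideal[, 2] + centre_nm[2])
  attr(out, "spec") <- spec
  out
}
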