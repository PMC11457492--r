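## Configuration, orchestration and shared descriptive statistics.
##
## A single YAML (or JSON) config drives a full simulate -> analyze run;
## every stage draws its randomness from a seed derived from the one global
## seed (stage_seed = global * 101 + 10007 * stage index, modulo 2^31 - 1),
## so any stage is independently reproducible.

stage_order <- c("simulate", "packing", "fft", "network", "linescan")

stage_schema <- list(
  simulate = c("lattice", "render", "network", "profiles"),
  packing = c("image", "points", "radius_nm", "expected_spacing_nm",
              "polarity"),
  fft = c("image", "points", "mode", "spacing_range_nm", "polarity",
          "tol_nm"),
  network = c("actin", "mt", "dilation_radius_vox", "min_length_um",
              "depths_um"),
  linescan = c("profiles_csv", "model", "normalize")
)

lattice_keys <- c("lattice_kind", "spacing_nm", "jitter_sd_nm",
                  "vacancy_fraction", "bundle_radius_nm", "n_points")
render_keys <- c("pixel_size_nm", "psf_sigma_nm", "noise_sd", "polarity",
                 "image_shape_px", "background_level", "contrast")
network_keys <- c("volume_shape_vox", "voxel_size_nm", "n_actin", "n_mt",
                  "pitch_mean_deg", "pitch_sd_deg", "length_um_range",
                  "paired_fraction", "pair_offset_nm", "avoid_overlap")
profile_keys <- c("model", "params", "axis_length_um", "n_samples",
                  "noise_sd", "n_profiles")

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")))
  }
  invisible(block)
}

#' Read and validate a pipeline run configuration
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list with
#'   elements `seed`, `out_dir` and `stages`.
#' @return The validated config list (class `tm_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("no such config: %s", config))
    config <- yaml::read_yaml(config)
  }
  check_keys(config, c("seed", "out_dir", "stages"), "config")
  if (is.null(config$stages) || !length(config$stages)) {
    abort("config has no stages")
  }
  bad <- setdiff(names(config$stages), stage_order)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  for (st in names(config$stages)) {
    check_keys(config$stages[[st]] %||% list(), stage_schema[[st]],
               sprintf("stage '%s'", st))
  }
  sim <- config$stages$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$lattice)) check_keys(sim$lattice, lattice_keys,
                                          "simulate.lattice")
    if (!is.null(sim$render)) check_keys(sim$render, render_keys,
                                         "simulate.render")
    if (!is.null(sim$network)) check_keys(sim$network, network_keys,
                                          "simulate.network")
    if (!is.null(sim$profiles)) check_keys(sim$profiles, profile_keys,
                                           "simulate.profiles")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("tm_config", "list"))
}

stage_seed <- function(global_seed, stage) {
  idx <- match(stage, stage_order)
  as.integer((as.numeric(global_seed) * 101 + 10007 * idx) %%
               (2^31 - 1))
}

#' Canonical hash of a configuration
#'
#' Serialises the config as JSON with recursively sorted keys and returns
#' its MD5, so the hash is stable under key reordering.
#'
#' @param config A config list.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(nzchar(names(x)))) {
        x <- x[order(names(x))]
      }
      lapply(x, sort_rec)
    } else x
  }
  canonical <- jsonlite::toJSON(sort_rec(unclass(config)),
                                auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canonical, tmp)
  unname(tools::md5sum(tmp))
}

#' Descriptive summary of a numeric vector
#'
#' Median (midpoint convention), IQR, range and a histogram, the reporting
#' style used for per-cell morphometrics.
#'
#' @param values Nonempty numeric vector of finite values.
#' @param bin_width Histogram bin width; defaults to the Freedman-Diaconis
#'   choice (falling back to range/10 for degenerate spreads).
#' @return A list with `n`, `median`, `iqr`, `min`, `max` and `histogram`
#'   (tibble `bin_left`, `bin_right`, `count`).
#' @export
summarize_values <- function(values, bin_width = NULL) {
  if (length(values) == 0) abort("empty input")
  if (any(!is.finite(values))) abort("values must be finite")
  if (is.null(bin_width)) {
    fd <- 2 * IQR(values) / max(length(values)^(1 / 3), 1)
    bin_width <- if (fd > 0) fd else max(diff(range(values)) / 10, 1)
  }
  lo <- floor(min(values) / bin_width) * bin_width
  breaks <- seq(lo, max(values) + bin_width, by = bin_width)
  cnt <- table(cut(values, breaks, include.lowest = TRUE, right = FALSE))
  list(n = length(values),
       median = median_mid(values),
       iqr = IQR(values),
       min = min(values), max = max(values),
       histogram = tibble(bin_left = head(breaks, -1),
                          bin_right = breaks[-1],
                          count = as.integer(cnt)))
}

## --- stage runners ---------------------------------------------------------

run_stage_simulate <- function(cfg, out, seed) {
  manifest <- character(0)
  stats <- list()
  sim <- cfg$stages$simulate
  if (!is.null(sim$lattice)) {
    ls_args <- sim$lattice
    spec <- do.call(lattice_spec, c(ls_args, list(seed = seed)))
    pts <- gen_lattice_points(spec)
    write_points_csv(pts, file.path(out, "points_truth.csv"))
    manifest <- c(manifest, file.path(out, "points_truth.csv"))
    if (!is.null(sim$render)) {
      rs <- do.call(render_spec, c(sim$render, list(seed = seed + 1L)))
      img <- render_cross_section(pts, rs)
      write_image_tiff(img, file.path(out, "cross_section.tif"))
      manifest <- c(manifest, file.path(out, "cross_section.tif"),
                    file.path(out, "cross_section.json"))
    }
    stats$n_lattice_points <- nrow(pts)
  }
  if (!is.null(sim$network)) {
    ns <- do.call(network3d_spec, c(sim$network, list(seed = seed + 2L)))
    net <- gen_network_volume(ns)
    write_volume_tiff(net$actin, file.path(out, "actin.tif"))
    write_volume_tiff(net$mt, file.path(out, "microtubule.tif"))
    write_points_csv(net$truth, file.path(out, "network_truth.csv"))
    manifest <- c(manifest, file.path(out, c("actin.tif", "actin.json",
                                             "microtubule.tif",
                                             "microtubule.json",
                                             "network_truth.csv")))
    stats$median_truth_pitch_deg <-
      summarize_values(net$truth$pitch_deg)$median
  }
  if (!is.null(sim$profiles)) {
    pr <- sim$profiles
    n_prof <- pr$n_profiles %||% 1L
    pr$n_profiles <- NULL
    profs <- purrr::map_dfr(seq_len(n_prof), function(i) {
      spec <- do.call(profile_spec, c(pr, list(seed = seed + 10L + i)))
      dplyr::mutate(gen_profile(spec), profile = i)
    })
    write_points_csv(profs, file.path(out, "profiles.csv"))
    manifest <- c(manifest, file.path(out, "profiles.csv"))
    stats$n_profiles <- n_prof
  }
  list(manifest = manifest, stats = stats)
}

run_stage_packing <- function(cfg, out, seed) {
  st <- cfg$stages$packing %||% list()
  pts <- if (!is.null(st$points)) {
    read_points_csv(st$points)
  } else {
    img_path <- st$image %||% file.path(out, "cross_section.tif")
    img <- read_image_tiff(img_path)
    detect_centers(img, st$expected_spacing_nm %||% 9.2,
                   polarity = st$polarity %||% "dark_filaments")
  }
  graph <- build_neighbor_graph(pts, st$radius_nm %||% 12)
  summ <- summarize_packing(pts, graph)
  write_points_csv(pts, file.path(out, "points.csv"))
  write_points_csv(graph, file.path(out, "edges.csv"))
  js <- c(as.list(glance(summ)),
          list(radius_nm = attr(graph, "radius_nm"),
               diameter_offset = "min enclosing circle + one spacing",
               nn_count_histogram = summ$nn_count_histogram[[1]]))
  jsonlite::write_json(js, file.path(out, "packing_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  list(manifest = file.path(out, c("points.csv", "edges.csv",
                                   "packing_summary.json")),
       stats = list(median_triplet_angle_deg =
                      summ$median_triplet_angle_deg,
                    estimated_spacing_nm = summ$estimated_spacing_nm))
}

run_stage_fft <- function(cfg, out, seed) {
  st <- cfg$stages$fft %||% list()
  img_path <- st$image %||% file.path(out, "cross_section.tif")
  img <- read_image_tiff(img_path)
  spec <- power_spectrum(img)
  rng <- unlist(st$spacing_range_nm %||% c(7, 12))
  refl <- detect_reflections(spec, rng)
  write_points_csv(as_tibble(refl), file.path(out, "reflections.csv"))
  manifest <- file.path(out, "reflections.csv")
  stats <- list(n_reflections = nrow(refl))
  res_js <- list(n_reflections = nrow(refl),
                 ring_radius_nm_inv = attr(refl, "ring_radius_nm_inv"))
  if (nrow(refl) > 0) {
    mode <- st$mode %||% "circular"
    filt <- lattice_filter(img, refl, mode = mode,
                           polarity = st$polarity %||% "dark_filaments")
    write_image_tiff(filt$filtered, file.path(out, "filtered.tif"))
    write_image_tiff(tm_image(filt$highlighted_mask * 1,
                              img$pixel_size_nm),
                     file.path(out, "highlighted_mask.tif"))
    manifest <- c(manifest,
                  file.path(out, c("filtered.tif", "filtered.json",
                                   "highlighted_mask.tif",
                                   "highlighted_mask.json")))
    pts_path <- st$points %||% file.path(out, "points_truth.csv")
    if (file.exists(pts_path)) {
      pts <- read_points_csv(pts_path)
      frac <- highlighted_fraction(filt, pts,
                                   tol_nm = st$tol_nm %||% 0)
      res_js$highlighted_fraction <- frac
      stats$highlighted_fraction <- frac
    }
  }
  jsonlite::write_json(res_js, file.path(out, "fft_result.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = c(manifest, file.path(out, "fft_result.json")),
       stats = stats)
}

run_stage_network <- function(cfg, out, seed) {
  st <- cfg$stages$network %||% list()
  actin <- read_volume_tiff(st$actin %||% file.path(out, "actin.tif"))
  mt <- read_volume_tiff(st$mt %||% file.path(out, "microtubule.tif"))
  traces <- trace_polymers(actin, st$min_length_um %||% 0.5)
  mt_traces <- trace_polymers(mt, st$min_length_um %||% 0.5)
  inter <- interaction_map(actin, mt,
                           st$dilation_radius_vox %||% 4L,
                           traces = traces)
  tr_out <- dplyr::select(dplyr::bind_rows(
    dplyr::mutate(traces, channel = "actin"),
    dplyr::mutate(mt_traces, channel = "microtubule")),
    "channel", "id", "length_um", "pitch_deg", "pitch_end_to_end_deg")
  write_points_csv(tr_out, file.path(out, "traces.csv"))
  write_points_csv(inter$segments, file.path(out, "interactions.csv"))
  js <- c(as.list(glance(inter)),
          list(median_actin_pitch_deg = median_mid(traces$pitch_deg),
               median_mt_pitch_deg = if (nrow(mt_traces))
                 median_mid(mt_traces$pitch_deg) else NA))
  jsonlite::write_json(js, file.path(out, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = file.path(out, c("traces.csv", "interactions.csv",
                                   "network_summary.json")),
       stats = list(percent_interacting = inter$percent_interacting,
                    median_actin_pitch_deg =
                      median_mid(traces$pitch_deg)))
}

run_stage_linescan <- function(cfg, out, seed) {
  st <- cfg$stages$linescan %||% list()
  path <- st$profiles_csv %||% file.path(out, "profiles.csv")
  if (!file.exists(path)) abort(sprintf("no such profile table: %s", path))
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!"profile" %in% names(tb)) tb$profile <- 1L
  profs <- split(tb[c("arclength_um", "intensity")], tb$profile)
  if (isTRUE(st$normalize)) profs <- purrr::map(profs, normalize_profile)
  model <- st$model %||% "lognormal"
  fits <- purrr::map(profs, fit_profile, model = model)
  peaks <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(glance(f), profile = nm, .before = 1)
  })
  write_points_csv(peaks, file.path(out, "peak_table.csv"))
  jsonlite::write_json(purrr::map(fits, function(f) {
    list(model = f$model, params = as.list(f$params), rss = f$rss,
         converged = f$converged, peak_position_um = f$peak_position_um)
  }), file.path(out, "fits.json"), auto_unbox = TRUE, digits = NA)
  list(manifest = file.path(out, c("peak_table.csv", "fits.json")),
       stats = list(n_fits = length(fits),
                    median_peak_um =
                      median_mid(peaks$peak_position_um[
                        !is.na(peaks$peak_position_um)])))
}

#' Run a configured simulate/analyze pipeline
#'
#' Executes the requested stages in dependency order (simulation first),
#' writing every artifact under the output directory and a deterministic
#' `run_report.json` (no timestamps, so fixed-seed runs are byte
#' reproducible). A failing stage aborts downstream stages; the report
#' records the error and any completed stages.
#'
#' @param config Path to a YAML/JSON config or a config list; see
#'   [read_run_config()].
#' @param out_dir Output directory override.
#' @return The run report list (class `tm_report`), invisibly written to
#'   `run_report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  runners <- list(simulate = run_stage_simulate,
                  packing = run_stage_packing,
                  fft = run_stage_fft,
                  network = run_stage_network,
                  linescan = run_stage_linescan)
  todo <- intersect(stage_order, names(cfg$stages))
  report <- list(package_version =
                   as.character(utils::packageVersion("tuftmorph")),
                 seed = cfg$seed,
                 config_hash = config_hash(cfg),
                 stages = list())
  failed <- FALSE
  for (st in todo) {
    if (failed) {
      report$stages[[st]] <- list(status = "skipped")
      next
    }
    sseed <- stage_seed(cfg$seed, st)
    log_msg("stage %s (seed %d)", st, sseed)
    res <- tryCatch(
      with_seed(sseed, runners[[st]](cfg, out, sseed)),
      error = function(e) e)
    if (inherits(res, "error")) {
      log_msg("stage %s FAILED: %s", st, conditionMessage(res))
      report$stages[[st]] <- list(status = "error",
                                  message = conditionMessage(res))
      failed <- TRUE
    } else {
      stopifnot(all(file.exists(res$manifest)))
      report$stages[[st]] <- list(status = "ok",
                                  manifest = basename(res$manifest),
                                  stats = res$stats)
      log_msg("stage %s ok (%d artifact(s))", st, length(res$manifest))
    }
  }
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(report, class = c("tm_report", "list"))
}
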