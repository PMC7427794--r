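#' Run configuration
#'
#' All tunable thresholds of the pipeline in one nested list, echoed verbatim
#' (with a hash) into every output file.
#'
#' * `orientation$angle_step_deg` (1): angular bin width of the spectrum.
#' * `orientation$f_min_per_um`, `f_max_per_um` (1/20, 1/(4 px)): radial band.
#' * `orientation$aniso_threshold` (0.15): isotropy decision on max(AI2, AI4).
#' * `orientation$secondary_ratio` (0.3), `ortho_tolerance_deg` (15): biaxial
#'   call.
#' * `orientation$roi`: optional `c(x0, y0, x1, y1)` lateral crop.
#' * `segmentation$change_threshold_deg` (30): new-lamella trigger.
#' * `segmentation$min_rate_deg_per_lamella` (3), `smooth_window` (3):
#'   rotated-zone rule.
#' * `bands$min_separation_um` (10), `prominence_k` (3),
#'   `background_window_um` (50).
#'
#' @param pixel_um pixel pitch used for the frequency-band default.
#' @export
default_run_config <- function(pixel_um = 0.44) {
  list(
    orientation = list(angle_step_deg = 1, f_min_per_um = 1 / 20,
                       f_max_per_um = 1 / (4 * pixel_um),
                       aniso_threshold = 0.15, secondary_ratio = 0.3,
                       ortho_tolerance_deg = 15, roi = NULL),
    segmentation = list(change_threshold_deg = 30,
                        min_rate_deg_per_lamella = 3, smooth_window = 3L),
    bands = list(min_separation_um = 10, prominence_k = 3,
                 background_window_um = 50)
  )
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the defaults; unknown keys raise an
#' error.
#'
#' @param path YAML file.
#' @param pixel_um pixel pitch for the defaults.
#' @export
read_run_config <- function(path, pixel_um = 0.44) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config(pixel_um)
  for (sec in names(y)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (k in names(y[[sec]])) {
      if (!k %in% names(cfg[[sec]])) stop("unknown config key: ", sec, "$", k)
      cfg[[sec]][[k]] <- y[[sec]][[k]]
    }
  }
  cfg
}

#' Stable hash of a configuration
#'
#' A rolling polynomial hash over the deparsed configuration, used to stamp
#' outputs with the exact configuration that produced them (provenance only,
#' not cryptographic).
#'
#' @param config a configuration list.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(config, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate a stack and write it with its ground truth
#'
#' Renders a preset or explicit schedule and writes `stack.tif` and
#' `truth.json` (every ground-truth field needed for recovery testing) to
#' `out_dir`.
#'
#' @param preset preset name for [preset_schedule()]; ignored when `schedule`
#'   is given.
#' @param schedule a `stack_schedule`, or a YAML file path for
#'   [read_schedule_yaml()].
#' @param params a [texture_params()] list; `seed` overrides its seed.
#' @param seed optional seed override.
#' @param out_dir output directory.
#' @param size_px plane size.
#' @return (invisibly) the truth record, with `$paths`.
#' @export
run_simulate <- function(preset = NULL, schedule = NULL,
                         params = texture_params(), seed = NULL,
                         out_dir = ".", size_px = c(256L, 256L)) {
  if (is.null(schedule)) {
    if (is.null(preset)) stop("either a preset name or a schedule is required")
    schedule <- preset_schedule(preset)
  } else if (is.character(schedule)) {
    sy <- read_schedule_yaml(schedule)
    schedule <- sy$schedule
    if (!is.null(sy$params)) params <- sy$params
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  gen <- make_stack(schedule, params, size_px)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stack_path <- file.path(out_dir, "stack.tif")
  truth_path <- file.path(out_dir, "truth.json")
  write_stack(gen$stack, stack_path)
  truth <- gen$truth
  truth$params <- params
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns",
                       pretty = TRUE)
  truth$paths <- c(stack = stack_path, truth = truth_path)
  invisible(truth)
}

#' Analyze a stack end to end and write all result files
#'
#' Reads (or accepts) a stack, computes the per-plane orientation profile and
#' the stromal metrics, and writes `planes.csv`, `metrics.json` and optionally
#' `fft_stack.tif` (+ axis sidecar CSV) to `out_dir`.  Outputs are
#' deterministic for a fixed input and configuration.
#'
#' @param stack an [image_stack] or a TIFF path.
#' @param config a run configuration, see [default_run_config()].
#' @param out_dir output directory.
#' @param z_step_um,pixel_um calibration used when `stack` is a path.
#' @param export_fft also write the log-scaled FFT power stack.
#' @return (invisibly) the metrics list.
#' @export
run_analyze <- function(stack, config = NULL, out_dir = ".",
                        z_step_um = 2, pixel_um = 0.44, export_fft = FALSE) {
  if (is.character(stack)) stack <- read_stack(stack, z_step_um, pixel_um)
  if (is.null(config)) config <- default_run_config(stack$meta$pixel_um)
  if (stack$meta$n_planes < 2L)
    stop("insufficient depth: at least 2 planes are required for depth metrics")
  profile <- analyze_stack(stack, config, keep_power = export_fft)
  metrics <- stroma_metrics(profile, stack$meta, config)
  write_metrics(metrics, profile, out_dir)
  if (export_fft)
    export_fft_stack(attr(profile, "power_images"), profile,
                     file.path(out_dir, "fft_stack.tif"))
  invisible(metrics)
}

#' Band analysis of a cross-section image
#'
#' @param image a [cross_section_image()] or a grayscale TIFF path.
#' @param pixel_um,depth_axis calibration used when `image` is a path.
#' @param config run configuration (the `bands` section is used).
#' @param out_dir if non-`NULL`, writes `bands.json`.
#' @return (invisibly) the [count_bands()] result.
#' @export
run_bands <- function(image, pixel_um = 0.78, depth_axis = "rows",
                      config = default_run_config(), out_dir = NULL) {
  if (is.character(image)) {
    pages <- .read_tiff_pages(image)
    if (length(dim(pages[[1L]])) > 2L) stop("cross-section must be grayscale")
    image <- cross_section_image(pages[[1L]], pixel_um, depth_axis)
  }
  bc <- config$bands
  prof <- depth_intensity_profile(image,
                                  background_window_um = bc$background_window_um)
  bands <- count_bands(prof, bc$min_separation_um, bc$prominence_k)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    out <- bands
    out$config_hash <- config_hash(config)
    jsonlite::write_json(out, file.path(out_dir, "bands.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bands)
}
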