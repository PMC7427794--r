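#' Image stack container with physical calibration
#'
#' An `image_stack` holds a 3D grayscale intensity volume together with its
#' acquisition geometry.  Plane 1 of the array is the epithelial-most plane;
#' depth increases with plane index, matching en-face SHG acquisition from the
#' epithelial towards the endothelial surface.  Calibration is supplied by the
#' caller (defaults mirror common SHG acquisition: 2 um z-step, 0.44 um/pixel);
#' embedded TIFF tags are never trusted over the caller.
#'
#' @param voxels numeric array `height x width x n_planes` of non-negative
#'   intensities (arbitrary units).  A matrix is treated as a single plane.
#' @param z_step_um axial step between planes in micrometres (> 0).
#' @param pixel_um lateral pixel pitch in micrometres (> 0).
#' @param bits nominal bit depth (8 or 16), used when writing TIFFs.
#' @return an object of class `image_stack` with elements `voxels` and `meta`
#'   (`z_step_um`, `pixel_um`, `n_planes`, `height_px`, `width_px`, `bits`).
#' @export
image_stack <- function(voxels, z_step_um = 2, pixel_um = 0.44, bits = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L) stop("voxels must be a height x width x planes array")
  if (!is.numeric(z_step_um) || z_step_um <= 0) stop("z_step_um must be positive")
  if (!is.numeric(pixel_um) || pixel_um <= 0) stop("pixel_um must be positive")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  d <- dim(voxels)
  meta <- list(z_step_um = z_step_um, pixel_um = pixel_um,
               n_planes = d[3L], height_px = d[1L], width_px = d[2L],
               bits = as.integer(bits))
  structure(list(voxels = voxels, meta = meta), class = "image_stack")
}

#' Total stromal thickness spanned by a stack
#'
#' @param x an `image_stack` or its `meta` list.
#' @return `(n_planes - 1) * z_step_um`, in micrometres.
#' @export
total_thickness_um <- function(x) {
  meta <- if (inherits(x, "image_stack")) x$meta else x
  (meta$n_planes - 1) * meta$z_step_um
}

#' @export
print.image_stack <- function(x, ...) {
  m <- x$meta
  cat(sprintf("image_stack: %d planes of %dx%d px, z-step %g um, pixel %g um (thickness %g um)\n",
              m$n_planes, m$height_px, m$width_px, m$z_step_um, m$pixel_um,
              total_thickness_um(m)))
  invisible(x)
}

#' Single cross-section image
#'
#' Holds one grayscale SHG cross-section (plane perpendicular to the corneal
#' surface).  `depth_axis` states which image axis runs from epithelium to
#' endothelium.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_um pixel pitch along the depth axis in micrometres.
#' @param depth_axis `"rows"` (depth increases with row index) or `"columns"`.
#' @export
cross_section_image <- function(pixels, pixel_um, depth_axis = c("rows", "columns")) {
  depth_axis <- match.arg(depth_axis)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_um) || pixel_um <= 0) stop("pixel_um must be positive")
  structure(list(pixels = pixels, pixel_um = pixel_um, depth_axis = depth_axis),
            class = "cross_section_image")
}

.read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Read a grayscale TIFF z-stack
#'
#' Reads a single- or multi-page grayscale TIFF (8 or 16 bit) and attaches the
#' physical calibration.  Intensities are preserved bit-exact (no rescaling).
#' Non-grayscale or mixed-shape pages raise an error naming the offending page.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return an [image_stack].
#' @export
read_stack <- function(path, z_step_um = 2, pixel_um = 0.44) {
  pages <- .read_tiff_pages(path)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) > 2L)
      stop(sprintf("page %d of %s is not grayscale (%d channels)",
                   i, path, dim(pages[[i]])[3L]))
    if (!identical(dim(pages[[i]]), dim(pages[[1L]])))
      stop(sprintf("page %d of %s has shape %s, expected %s", i, path,
                   paste(dim(pages[[i]]), collapse = "x"),
                   paste(dim(pages[[1L]]), collapse = "x")))
  }
  vox <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) vox[, , i] <- pages[[i]]
  bits <- if (max(vox) > 255) 16L else 8L
  image_stack(vox, z_step_um = z_step_um, pixel_um = pixel_um, bits = bits)
}

#' Write a stack as a multi-page grayscale TIFF
#'
#' Voxels must be integer-valued within the stack's bit depth; the written file
#' round-trips bit-exact through [read_stack()].
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  bits <- stack$meta$bits
  maxv <- 2^bits - 1
  vox <- stack$voxels
  if (any(vox != round(vox)) || max(vox) > maxv)
    stop(sprintf("voxels must be integers in [0, %d] to write a %d-bit TIFF", maxv, bits))
  pages <- lapply(seq_len(stack$meta$n_planes),
                  function(i) vox[, , i] / maxv)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(NULL)
}

#' Export the per-plane FFT power stack for external 3D rendering
#'
#' Writes one log-scaled, max-normalised power image per plane as a multi-page
#' TIFF, plus a sidecar CSV of per-plane dominant axes, replacing the manual
#' segmentation / surface-rendering step of interactive workflows.
#'
#' @param power_images list of 2D power matrices (one per plane, equal shapes).
#' @param profile the per-plane orientation table from [analyze_stack()]
#'   (columns `z_um`, `class`, `axis1_deg`); may be `NULL` to skip the CSV.
#' @param path output TIFF path; the CSV is written next to it as
#'   `<path>_axes.csv`.
#' @export
export_fft_stack <- function(power_images, profile = NULL, path) {
  if (length(power_images) == 0L) stop("no power images to export")
  shp <- dim(power_images[[1L]])
  for (i in seq_along(power_images))
    if (!identical(dim(power_images[[i]]), shp))
      stop(sprintf("power image %d has mismatched shape", i))
  pages <- lapply(power_images, function(p) {
    lp <- log1p(p)
    m <- max(lp)
    if (m > 0) lp / m else lp
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(profile)) {
    ax <- ifelse(profile$class == "isotropic", "",
                 formatC(profile$axis1_deg, format = "fg", digits = 8))
    utils::write.csv(
      data.frame(plane = seq_len(nrow(profile)), z_um = profile$z_um,
                 class = profile$class, axis_deg = ax),
      paste0(path, "_axes.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Write analysis results to disk
#'
#' Emits `metrics.json` (the stroma metrics with config echo, numbers written
#' losslessly) and `planes.csv` with columns exactly
#' `z_um,class,axis1_deg,axis2_deg,AI2,AI4`.  Isotropic planes have empty axis
#' fields.
#'
#' @param metrics a list as returned by [stroma_metrics()].
#' @param profile the per-plane orientation table from [analyze_stack()].
#' @param out_dir output directory (created if missing).
#' @export
write_metrics <- function(metrics, profile, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "fg", digits = 10))
  tab <- data.frame(z_um = fmt(profile$z_um),
                    class = profile$class,
                    axis1_deg = ifelse(profile$class == "isotropic", "",
                                       fmt(profile$axis1_deg)),
                    axis2_deg = ifelse(profile$class == "biaxial",
                                       fmt(profile$axis2_deg), ""),
                    AI2 = fmt(profile$AI2), AI4 = fmt(profile$AI4))
  utils::write.csv(tab, file.path(out_dir, "planes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
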