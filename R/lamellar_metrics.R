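#' Lamellar segmentation and stromal metrics
#'
#' Converts the per-plane orientation depth profile into lamellae and computes
#' the three stage metrics of the orthogonal/rotated stroma: lamellar
#' orthogonality (mean axial angle between adjacent lamellae), total angular
#' displacement (within-family unwrapped rotation from epithelium to
#' endothelium), and the rotated fraction of total stromal thickness.
#'
#' @name lamellar_metrics
NULL

#' Segment the depth profile into lamellae
#'
#' Greedy run segmentation over the non-isotropic planes, in depth order: a
#' new lamella starts when the axial distance between a plane's axis and the
#' current run's circular axial median exceeds `change_threshold_deg`.
#' Biaxial planes contribute the axis nearer the current run's median (the
#' other axis belongs to the orthogonal family and is picked up when that
#' family's lamellae are traversed).  Isotropic planes are excluded from runs
#' but counted in total stromal thickness; they are reported via the
#' `n_isotropic` attribute.
#'
#' @param profile per-plane orientation table from [analyze_stack()].
#' @param meta stack metadata (taken from the profile's attribute when
#'   omitted); needs `z_step_um` and `n_planes`.
#' @param change_threshold_deg axial change starting a new lamella.
#' @return data.frame of lamellae (`z_start_um`, `z_end_um`, `axis_deg`,
#'   `n_planes`) with attributes `n_isotropic` and `total_thickness_um`.
#' @export
segment_lamellae <- function(profile, meta = attr(profile, "meta"),
                             change_threshold_deg = 30) {
  if (nrow(profile) == 0L) stop("empty profile")
  if (is.null(meta)) stop("stack metadata required")
  total <- (meta$n_planes - 1) * meta$z_step_um
  ori <- profile[profile$class != "isotropic", , drop = FALSE]
  n_iso <- nrow(profile) - nrow(ori)
  mk <- function(lams) {
    out <- if (length(lams) == 0L)
      data.frame(z_start_um = numeric(), z_end_um = numeric(),
                 axis_deg = numeric(), n_planes = integer())
    else do.call(rbind, lams)
    attr(out, "n_isotropic") <- n_iso
    attr(out, "total_thickness_um") <- total
    attr(out, "meta") <- meta
    out
  }
  if (nrow(ori) == 0L) {
    warning("all planes isotropic; no lamellae")
    return(mk(list()))
  }
  lams <- list()
  run_angles <- c(); run_z <- c()
  close_run <- function() {
    z_end <- min(max(run_z) + meta$z_step_um, total)
    if (length(run_z) == 1L && max(run_z) == total) z_end <- total
    data.frame(z_start_um = min(run_z), z_end_um = z_end,
               axis_deg = axial_median(run_angles),
               n_planes = length(run_z))
  }
  for (i in seq_len(nrow(ori))) {
    axes <- ori$axis1_deg[i]
    if (ori$class[i] == "biaxial" && is.finite(ori$axis2_deg[i]))
      axes <- c(axes, ori$axis2_deg[i])
    if (length(run_angles) == 0L) {
      run_angles <- axes[1L]; run_z <- ori$z_um[i]
      next
    }
    med <- axial_median(run_angles)
    d <- axial_difference(axes, med)
    k <- which.min(d)
    if (d[k] <= change_threshold_deg) {
      run_angles <- c(run_angles, axes[k]); run_z <- c(run_z, ori$z_um[i])
    } else {
      lams[[length(lams) + 1L]] <- close_run()
      run_angles <- axes[1L]; run_z <- ori$z_um[i]
    }
  }
  lams[[length(lams) + 1L]] <- close_run()
  mk(lams)
}

#' Assign lamellae to orthogonal families and unwrap their angles
#'
#' Lamella 1 founds family A.  Each subsequent lamella joins the family whose
#' running track angle is axially nearer (family B's track is seeded 90
#' degrees from A), and its unwrapped angle continues that family's track by
#' the nearest 180-congruent value, separating the orthogonal alternation from
#' the slow within-family rotation.  Equidistant cases (within 1e-9) fall back
#' to alternating the previous lamella's family.
#'
#' @param lamellae output of [segment_lamellae()].
#' @return the same data.frame with `family` and `unwrapped_deg` columns.
#' @export
assign_families_and_unwrap <- function(lamellae) {
  if (nrow(lamellae) < 1L) stop("no lamellae")
  uw <- .unwrap_axes(lamellae$axis_deg)
  lamellae$family <- uw$family
  lamellae$unwrapped_deg <- uw$unwrapped_deg
  lamellae
}

#' Mean adjacent-pair lamellar orthogonality
#'
#' @param lamellae lamella table (>= 2 rows).
#' @return list with `orthogonality_deg` (mean of the axial angles between
#'   consecutive lamella pairs, in \[0, 90\]) and `pairs` (per-pair angles).
#' @export
orthogonality_stats <- function(lamellae) {
  n <- nrow(lamellae)
  if (n < 2L) stop("orthogonality needs at least 2 lamellae")
  pairs <- axial_difference(lamellae$axis_deg[-n], lamellae$axis_deg[-1L])
  list(orthogonality_deg = mean(pairs), pairs = pairs)
}

#' Total angular displacement of the stroma
#'
#' For each family the displacement is the absolute difference between the
#' last and first unwrapped angles of its track; the reported value is the
#' mean over the families with at least two lamellae.  The sign of the common
#' rotation (chirality) is reported separately.
#'
#' @param lamellae lamella table with family tracks
#'   (see [assign_families_and_unwrap()]).
#' @return list with `angular_displacement_deg`, `family_displacements`
#'   (signed, per family) and `rotation_sign`.
#' @export
angular_displacement <- function(lamellae) {
  if (is.null(lamellae$family)) stop("family tracks not built")
  signed <- c(A = NA_real_, B = NA_real_)
  for (f in c("A", "B")) {
    u <- lamellae$unwrapped_deg[lamellae$family == f]
    if (length(u) >= 2L) signed[f] <- u[length(u)] - u[1L]
  }
  ok <- !is.na(signed)
  if (!any(ok)) stop("no family has 2 or more lamellae")
  list(angular_displacement_deg = mean(abs(signed[ok])),
       family_displacements = as.list(signed),
       rotation_sign = sign(mean(signed[ok])))
}

#' Locate the rotated zone and its depth fraction
#'
#' Each lamella's within-family step is the unwrapped difference from the
#' previous lamella of the same family.  Absolute steps are smoothed with a
#' centred moving average (window `smooth_window` lamellae, missing values
#' ignored); the rotated zone is the longest contiguous run of lamellae whose
#' smoothed step is at least `min_rate_deg_per_lamella`, extended one lamella
#' towards the epithelium because a qualifying step accrues across the
#' preceding (orthogonal) lamella.  The fraction is relative to total stromal
#' thickness (isotropic planes included in the denominator).
#'
#' @param lamellae lamella table with family tracks.
#' @param total_thickness_um total stromal thickness (defaults to the
#'   attribute set by [segment_lamellae()]).
#' @param min_rate_deg_per_lamella rotation-rate threshold.
#' @param smooth_window smoothing window, lamellae.
#' @return list with `rotated_span_um` (`c(start, end)` or `NULL`) and
#'   `rotated_fraction_pct`.
#' @export
rotated_zone <- function(lamellae,
                         total_thickness_um = attr(lamellae, "total_thickness_um"),
                         min_rate_deg_per_lamella = 3, smooth_window = 3L) {
  if (is.null(lamellae$family)) stop("family tracks not built")
  if (is.null(total_thickness_um) || total_thickness_um <= 0)
    stop("positive total thickness required")
  n <- nrow(lamellae)
  step <- rep(NA_real_, n)
  for (f in c("A", "B")) {
    j <- which(lamellae$family == f)
    if (length(j) >= 2L) step[j[-1L]] <- abs(diff(lamellae$unwrapped_deg[j]))
  }
  k <- (smooth_window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    w <- step[max(1L, i - k):min(n, i + k)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  qual <- !is.na(sm) & sm >= min_rate_deg_per_lamella
  if (!any(qual))
    return(list(rotated_span_um = NULL, rotated_fraction_pct = 0))
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- max(starts[best] - 1L, 1L)  # step accrues across the preceding lamella
  i2 <- ends[best]
  span <- c(lamellae$z_start_um[i1], lamellae$z_end_um[i2])
  list(rotated_span_um = span,
       rotated_fraction_pct = 100 * (span[2] - span[1]) / total_thickness_um)
}

#' Full stromal metrics from a depth profile
#'
#' Runs segmentation, family assignment and the three stage metrics, returning
#' the schema written to `metrics.json`.
#'
#' @param profile per-plane orientation table from [analyze_stack()].
#' @param meta stack metadata (defaults to the profile attribute).
#' @param config run configuration (defaults to the profile attribute, else
#'   [default_run_config()]); its `segmentation` entries supply
#'   `change_threshold_deg`, `min_rate_deg_per_lamella`, `smooth_window`.
#' @return list with `orthogonality_deg`, `orthogonality_pairs`,
#'   `angular_displacement_deg`, `family_displacements`, `rotation_sign`,
#'   `rotated_span_um`, `rotated_fraction_pct`, `n_lamellae`,
#'   `n_isotropic_planes`, `config_echo`.
#' @export
stroma_metrics <- function(profile, meta = attr(profile, "meta"),
                           config = NULL) {
  if (is.null(config)) config <- attr(profile, "config")
  if (is.null(config)) config <- default_run_config()
  sc <- config$segmentation
  lam <- segment_lamellae(profile, meta, sc$change_threshold_deg)
  base <- list(orthogonality_deg = NA_real_, orthogonality_pairs = numeric(0),
               angular_displacement_deg = NA_real_,
               family_displacements = list(A = NA_real_, B = NA_real_),
               rotation_sign = NA_real_, rotated_span_um = NULL,
               rotated_fraction_pct = NA_real_,
               n_lamellae = nrow(lam),
               n_isotropic_planes = attr(lam, "n_isotropic"),
               config_echo = config,
               config_hash = config_hash(config))
  if (nrow(lam) < 2L) return(base)
  lam <- assign_families_and_unwrap(lam)
  orth <- orthogonality_stats(lam)
  rz <- rotated_zone(lam, attr(lam, "total_thickness_um"),
                     sc$min_rate_deg_per_lamella, sc$smooth_window)
  base$orthogonality_deg <- orth$orthogonality_deg
  base$orthogonality_pairs <- orth$pairs
  if (max(table(lam$family)) >= 2L) {  # displacement needs a 2-lamella track
    disp <- angular_displacement(lam)
    base$angular_displacement_deg <- disp$angular_displacement_deg
    base$family_displacements <- disp$family_displacements
    base$rotation_sign <- disp$rotation_sign
  }
  base$rotated_span_um <- rz$rotated_span_um
  base$rotated_fraction_pct <- rz$rotated_fraction_pct
  base
}

#' Aggregate metrics over specimens
#'
#' @param metrics_list list of [stroma_metrics()] results.
#' @return data.frame `metric, mean, se, n`; `se` is the sample standard
#'   deviation over sqrt(n), `NA` when n < 2.
#' @export
aggregate_specimens <- function(metrics_list) {
  if (length(metrics_list) < 1L) stop("no specimens")
  fields <- c("orthogonality_deg", "angular_displacement_deg",
              "rotated_fraction_pct", "n_lamellae")
  do.call(rbind, lapply(fields, function(f) {
    v <- vapply(metrics_list, function(m) as.numeric(m[[f]]), numeric(1))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(metric = f,
               mean = if (n) mean(v) else NA_real_,
               se = if (n >= 2L) stats::sd(v) / sqrt(n) else NA_real_,
               n = n)
  }))
}
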