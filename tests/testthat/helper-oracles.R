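# Independent test oracles and small builders.  Nothing here is used by the
# package itself: the structure tensor exists only to cross-check the FFT
# orientation estimate, and the rotator defines its own explicit convention.

# Structure-tensor fiber axis with spectral (exact) derivatives.  The dominant
# gradient orientation is 0.5 * atan2(2 Jxy, Jxx - Jyy); the fiber axis is
# perpendicular to it.  Angles follow the package convention: degrees from the
# image row axis, y = row index, x = column index.
st_axis <- function(img) {
  H <- nrow(img); W <- ncol(img)
  freq <- function(n) {
    k <- 0:(n - 1)
    k[k >= n / 2] <- k[k >= n / 2] - n
    k / n
  }
  Fi <- stats::fft(img)
  gy <- Re(stats::fft(Fi * (2i * pi * matrix(freq(H), H, W)),
                      inverse = TRUE)) / (H * W)
  gx <- Re(stats::fft(Fi * (2i * pi * matrix(freq(W), H, W, byrow = TRUE)),
                      inverse = TRUE)) / (H * W)
  jxx <- mean(gx^2); jyy <- mean(gy^2); jxy <- mean(gx * gy)
  (0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90) %% 180
}

# Bilinear image rotation by delta degrees in the (x = column, y = row) frame:
# a fiber at axis a maps to axis a + delta (mod 180).  Returns the central
# crop_px x crop_px window, which stays inside the valid region for any delta.
rotate_image <- function(img, delta_deg, crop_px = 128L) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  d <- delta_deg * pi / 180
  yp <- matrix(seq_len(H) - cy, H, W)
  xp <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  xs <- cos(d) * xp + sin(d) * yp + cx
  ys <- -sin(d) * xp + cos(d) * yp + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 < W & y0 >= 1 & y0 < H
  idx <- function(yy, xx) (xx - 1L) * H + yy
  v <- rep(0, H * W)
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[idx(y0[ok], x0[ok])] +
    fx[ok] * (1 - fy[ok]) * img[idx(y0[ok], x0[ok] + 1L)] +
    (1 - fx[ok]) * fy[ok] * img[idx(y0[ok] + 1L, x0[ok])] +
    fx[ok] * fy[ok] * img[idx(y0[ok] + 1L, x0[ok] + 1L)]
  out <- matrix(v, H, W)
  r0 <- floor((H - crop_px) / 2); c0 <- floor((W - crop_px) / 2)
  out[(r0 + 1):(r0 + crop_px), (c0 + 1):(c0 + crop_px)]
}

# Build a per-plane orientation profile directly from known axes, as
# analyze_stack() would emit, for unit-testing the lamellar metrics without
# rendering textures.
mk_profile <- function(axes_deg, z_step_um = 2, class = NULL, axis2 = NULL) {
  n <- length(axes_deg)
  if (is.null(class)) class <- ifelse(is.na(axes_deg), "isotropic", "uniaxial")
  out <- data.frame(z_index = 0:(n - 1L), z_um = (0:(n - 1L)) * z_step_um,
                    class = class, axis1_deg = axes_deg %% 180,
                    axis2_deg = if (is.null(axis2)) NA_real_ else axis2 %% 180,
                    AI2 = 0.8, AI4 = 0.8, stringsAsFactors = FALSE)
  out$axis1_deg[class == "isotropic"] <- NA_real_
  attr(out, "meta") <- list(z_step_um = z_step_um, pixel_um = 0.44,
                            n_planes = n, height_px = 256L, width_px = 256L)
  out
}

# Orientation spectrum with unit impulses at given angles (1-degree grid).
delta_spectrum <- function(angles_at, weights = rep(1, length(angles_at))) {
  p <- numeric(180)
  p[round(angles_at) + 1L] <- weights
  orientation_spectrum(0:179, p)
}

# Brute-force scan for the two strongest local maxima of a spectrum vector
# (independent of the package's peak machinery).
brute_top2 <- function(p) {
  n <- length(p)
  prv <- c(n, 1:(n - 1)); nxt <- c(2:n, 1)
  idx <- which(p > p[prv] & p >= p[nxt])
  idx[order(-p[idx])][1:min(2, length(idx))]
}
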