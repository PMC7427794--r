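test_that("spectral convention maps a horizontal grating to fiber axis 0", {
  # intensity varies along columns (with row index), stripes run along rows
  img <- outer(cos(2 * pi * (0:255) * 10 / 256), rep(1, 256)) + 2
  s <- angular_power_spectrum(img, 0.44)
  expect_equal(s$angles_deg[which.max(s$power)], 0)
  expect_lt(axial_difference(detect_axes(s)$axis1_deg, 0), 1)
})

test_that("white noise yields a flat, isotropic spectrum", {
  set.seed(5)
  wn <- matrix(rnorm(512^2), 512)
  s <- angular_power_spectrum(wn, 0.44, radial_band = c(0.05, 1.0),
                              angle_step_deg = 2)
  expect_lt(max(s$power) / min(s$power), 1.5)
  det <- detect_axes(s)
  expect_equal(det$class, "isotropic")
})

test_that("synthetic fiber planes are recovered within 2 degrees", {
  p <- texture_params(seed = 11)  # defaults: snr 3, dispersion 8
  img <- make_fiber_plane(37, p)
  d <- detect_axes(angular_power_spectrum(img, 0.44))
  expect_equal(d$class, "uniaxial")
  expect_lt(axial_difference(d$axis1_deg, 37), 2)
  expect_lt(axial_difference(st_axis(img), 37), 3)  # oracle sanity
})

test_that("constant images give a degenerate (isotropic) spectrum", {
  s <- angular_power_spectrum(matrix(5, 64, 64), 0.44)
  expect_true(s$degenerate)
  expect_equal(detect_axes(s)$class, "isotropic")
  expect_error(angular_power_spectrum(matrix(0, 32, 32), 0.44), "64x64")
  expect_error(angular_power_spectrum(matrix(0, 64, 64), 0.44,
                                      radial_band = c(0.05, 5)), "Nyquist")
})

test_that("anisotropy index identities hold exactly", {
  one <- delta_spectrum(30)
  ai <- anisotropy_indices(one)
  expect_equal(unname(ai["AI2"]), 1)
  expect_equal(unname(ai["AI4"]), 1)

  pair <- delta_spectrum(c(30, 120))  # equal orthogonal pair
  ai <- anisotropy_indices(pair)
  expect_equal(unname(ai["AI2"]), 0, tolerance = 1e-12)
  expect_equal(unname(ai["AI4"]), 1)

  unif <- orientation_spectrum(0:179, rep(1, 180))
  ai <- anisotropy_indices(unif)
  expect_equal(unname(ai["AI2"]), 0, tolerance = 1e-12)
  expect_equal(unname(ai["AI4"]), 0, tolerance = 1e-12)

  expect_error(anisotropy_indices(orientation_spectrum(0:179, rep(0, 180))),
               "zero total power")
})

test_that("axis detection classifies constructed spectra", {
  d <- detect_axes(delta_spectrum(30))
  expect_equal(d$class, "uniaxial")
  expect_equal(d$axis1_deg, 30)

  d2 <- detect_axes(delta_spectrum(c(30, 120)))
  expect_equal(d2$class, "biaxial")
  expect_setequal(round(c(d2$axis1_deg, d2$axis2_deg)), c(30, 120))
  expect_equal(axial_difference(d2$axis1_deg, d2$axis2_deg), 90)

  # two Gaussian bumps, power ratio 0.4, separation 88 degrees
  ang <- 0:179
  bump <- function(c0, amp) amp * exp(-0.5 * (axial_difference(ang, c0) / 4)^2)
  spec <- orientation_spectrum(ang, bump(30, 1) + bump(118, 0.4))
  d3 <- detect_axes(spec)
  expect_equal(d3$class, "biaxial")
  # brute-force oracle agrees on the two peak locations
  top2 <- sort(ang[brute_top2(spec$power)])
  expect_equal(top2, c(30, 118))
  expect_lt(axial_difference(d3$axis1_deg, 30), 1.5)
  expect_lt(axial_difference(d3$axis2_deg, 118), 1.5)

  # same bumps at separation 60: outside the orthogonality tolerance
  d4 <- detect_axes(orientation_spectrum(ang, bump(30, 1) + bump(90, 0.4)))
  expect_equal(d4$class, "uniaxial")
})

test_that("orientation estimate is invariant to gain and offset", {
  img <- make_fiber_plane(73, texture_params(seed = 21))
  a1 <- detect_axes(angular_power_spectrum(img, 0.44))$axis1_deg
  a2 <- detect_axes(angular_power_spectrum(3.2 * img + 50, 0.44))$axis1_deg
  expect_lt(axial_difference(a1, a2), 0.3)
})

test_that("orientation estimate is equivariant under image rotation", {
  p <- texture_params(snr = 10, angular_dispersion_deg = 4, seed = 31)
  for (case in list(c(20, 25), c(0, 40), c(130, 15))) {
    img <- make_fiber_plane(case[1], p, size_px = c(384L, 384L))
    rot <- rotate_image(img, case[2])
    a <- detect_axes(angular_power_spectrum(rot, 0.44))$axis1_deg
    expect_lt(axial_difference(a, case[1] + case[2]), 2)
  }
})

test_that("anisotropy indices decrease monotonically with dispersion", {
  ladder <- c(2, 6, 12, 20, 35)
  ai2 <- ai4 <- numeric(length(ladder))
  for (i in seq_along(ladder)) {
    img <- make_fiber_plane(50, texture_params(angular_dispersion_deg = ladder[i],
                                               snr = Inf, seed = 41))
    ai <- anisotropy_indices(angular_power_spectrum(img, 0.44))
    ai2[i] <- ai["AI2"]; ai4[i] <- ai["AI4"]
  }
  expect_true(all(diff(ai2) < 0))
  expect_true(all(diff(ai4) < 0))
})

test_that("stack analysis returns one row per plane in depth order", {
  sched <- drift_schedule(n_lamellae = 10L, planes_per_lamella = 2L)
  gen <- make_stack(sched, texture_params(seed = 51))
  prof <- analyze_stack(gen$stack)
  expect_equal(nrow(prof), 20)
  expect_equal(prof$z_um, (0:19) * 2)
  err <- axial_difference(prof$axis1_deg, gen$truth$per_plane$axis_deg)
  expect_lt(max(err), 2)  # alternating 0/90 recovered plane-wise

  one <- image_stack(gen$stack$voxels[, , 1, drop = FALSE])
  expect_equal(nrow(analyze_stack(one)), 1)

  cfg <- default_run_config()
  cfg$orientation$roi <- c(1, 1, 500, 500)
  expect_error(analyze_stack(gen$stack, cfg), "roi out of bounds")
})
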