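test_that("texture generation is deterministic and seed-sensitive", {
  p <- texture_params(seed = 7)
  expect_identical(make_fiber_plane(30, p), make_fiber_plane(30, p))
  expect_false(identical(make_fiber_plane(30, p),
                         make_fiber_plane(30, texture_params(seed = 8))))
  sched <- drift_schedule(n_lamellae = 4L, planes_per_lamella = 2L)
  s1 <- make_stack(sched, p, size_px = c(64L, 64L))
  s2 <- make_stack(sched, p, size_px = c(64L, 64L))
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  s3 <- make_stack(sched, texture_params(seed = 8), size_px = c(64L, 64L))
  expect_false(identical(s1$stack$voxels, s3$stack$voxels))
  expect_identical(s1$truth$lamellae, s3$truth$lamellae)  # truth is seed-free
})

test_that("fiber planes elongate along the requested axis", {
  img <- make_fiber_plane(0, texture_params(snr = Inf, angular_dispersion_deg = 0,
                                            seed = 3))
  lag <- 4L
  along_rows <- cor(as.vector(img[, 1:(256 - lag)]), as.vector(img[, (lag + 1):256]))
  along_cols <- cor(as.vector(img[1:(256 - lag), ]), as.vector(img[(lag + 1):256, ]))
  expect_gt(along_rows, along_cols)  # autocorrelation decays slower along fibers
  expect_error(make_fiber_plane(0, texture_params(fiber_wavelength_um = 0.5)),
               "resolvable")
})

test_that("schedules map planes to lamellae and carry exact ground truth", {
  sched <- stack_schedule(data.frame(axis_deg = c(0, 90),
                                     thickness_um = c(10, 8)))
  expect_equal(sched$n_planes, 10)
  gen <- make_stack(sched, texture_params(seed = 5), size_px = c(64L, 64L))
  expect_equal(gen$truth$per_plane$axis_deg, c(rep(0, 5), rep(90, 5)))

  alt <- drift_schedule(n_lamellae = 8L, planes_per_lamella = 2L)
  expect_equal(alt$truth$total_displacement_deg, 0)

  expect_error(stack_schedule(data.frame(axis_deg = 0, thickness_um = 5)),
               "whole number")
  expect_error(stack_schedule(data.frame(axis_deg = 0, thickness_um = 1)),
               "below the z-step")
})

test_that("within-family drift accumulates as the brute-force unwrap predicts", {
  # 50 lamellae alternating families, +1.2 deg/lamella within-family drift:
  # family A runs 0 -> 57.6, family B runs 91.2 -> 148.8, both displaced 57.6
  i <- 0:49
  axes <- ifelse(i %% 2 == 0, 0, 90) + 1.2 * i
  thick <- c(rep(4, 49), 2)
  sched <- stack_schedule(data.frame(axis_deg = axes %% 180, thickness_um = thick))
  expect_equal(sched$truth$total_displacement_deg, 57.6)
  expect_equal(sched$truth$family_displacements$A, 57.6)
  expect_equal(sched$truth$family_displacements$B, 57.6)
})

test_that("schedule truth is self-consistent with the metrics-path unwrap", {
  set.seed(13)
  for (k in 1:5) {
    D <- runif(1, 20, 200)
    sched <- drift_schedule(displacement_deg = D, zone_lamellae = c(5L, 40L),
                            orthogonality_deg = runif(1, 84, 90),
                            jitter_deg = runif(1, 0, 1.5), jitter_seed = k)
    lam <- sched$lamellae
    lam2 <- assign_families_and_unwrap(lam[, c("z_start_um", "z_end_um",
                                               "axis_deg")])
    d <- angular_displacement(lam2)
    expect_equal(d$angular_displacement_deg, sched$truth$total_displacement_deg,
                 tolerance = 1e-8)
    expect_identical(lam2$family, lam$family)
  }
})

test_that("presets carry the published stage parameters as ground truth", {
  late <- preset_schedule("late_wound")
  expect_equal(late$truth$total_displacement_deg, 103.16)
  expect_lt(abs(late$truth$rotated_fraction_pct - 71.798), 1.5)  # lamellar grid
  expect_equal(preset_schedule("mid_wound")$truth$total_displacement_deg, 39.41)
  expect_equal(preset_schedule("E19")$truth$total_displacement_deg, 193.4)
  alt <- preset_schedule("alternating_only")
  expect_equal(alt$truth$total_displacement_deg, 0)
  expect_equal(alt$truth$rotated_fraction_pct, 0)
  expect_equal(alt$truth$orthogonality_deg, 90)
  expect_error(preset_schedule("early_wound"), "unknown preset")
})

test_that("wound regions replace only their box and validate bounds", {
  sched <- drift_schedule(n_lamellae = 4L, planes_per_lamella = 2L)
  p <- texture_params(seed = 9)
  base <- make_stack(sched, p, size_px = c(128L, 128L))
  noop <- make_wound_stack(sched, wound_spec(60, 60, 59, 59), p,
                           size_px = c(128L, 128L))
  expect_identical(noop$stack$voxels, base$stack$voxels)

  w <- wound_spec(33, 33, 96, 96, fill = "uniaxial", axis_deg = 90)
  gw <- make_wound_stack(sched, w, p, size_px = c(128L, 128L))
  expect_identical(gw$stack$voxels[1:32, 1:32, ], base$stack$voxels[1:32, 1:32, ])
  expect_false(identical(gw$stack$voxels[33:96, 33:96, ],
                         base$stack$voxels[33:96, 33:96, ]))
  expect_equal(unique(gw$truth$wound$class), "uniaxial")

  expect_error(make_wound_stack(sched, wound_spec(1, 1, 300, 300), p,
                                size_px = c(128L, 128L)), "out of stack bounds")
})

test_that("biaxial lamellae enforce near-orthogonal separation", {
  expect_error(lamella_spec(0, 4, "biaxial", 40), "75")
  ok <- lamella_spec(0, 4, "biaxial", 88)
  expect_equal(ok$class, "biaxial")
})

test_that("cross-sections are bright where the track lies in the section plane", {
  const <- drift_schedule(displacement_deg = 0)
  cs <- render_cross_section(const, 0, texture_params(seed = 2))
  expect_equal(alignment_crossings(const, 0), 1)  # one full-depth region
  expect_true(all(rowMeans(cs$pixels) > 50))      # bright at every depth
  expect_equal(alignment_crossings(const, 60), 0)

  sweep190 <- drift_schedule(displacement_deg = 190, zone_lamellae = c(4L, 16L))
  sweep100 <- drift_schedule(displacement_deg = 100, zone_lamellae = c(4L, 16L))
  expect_equal(alignment_crossings(sweep190, 0), 2)
  expect_equal(alignment_crossings(sweep100, 0), 1)

  cs1 <- render_cross_section(sweep190, 0, texture_params(seed = 2))
  cs2 <- render_cross_section(sweep190, 0, texture_params(seed = 2))
  expect_identical(cs1$pixels, cs2$pixels)
})
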