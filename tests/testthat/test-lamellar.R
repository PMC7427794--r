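test_that("greedy segmentation splits the profile at axis changes", {
  lam <- segment_lamellae(mk_profile(c(10, 10, 10, 100, 100)))
  expect_equal(nrow(lam), 2)
  expect_equal(lam$axis_deg, c(10, 100))
  expect_equal(lam$n_planes, c(3, 2))

  const <- segment_lamellae(mk_profile(rep(42, 12)))
  expect_equal(nrow(const), 1)
  expect_equal(const$z_start_um, 0)
  expect_equal(const$z_end_um, 22)  # full depth: (12 - 1) * 2 um

  alt <- segment_lamellae(mk_profile(rep(c(0, 0, 0, 0, 90, 90, 90, 90), 5)))
  expect_equal(nrow(alt), 10)

  expect_warning(lam0 <- segment_lamellae(mk_profile(rep(NA_real_, 5))),
                 "isotropic")
  expect_equal(nrow(lam0), 0)
  expect_equal(attr(lam0, "n_isotropic"), 5)
})

test_that("family assignment and unwrapping follow the nearer track", {
  lam <- assign_families_and_unwrap(segment_lamellae(mk_profile(c(0, 88, 2, 91))))
  expect_equal(lam$family, c("A", "B", "A", "B"))
  expect_equal(lam$unwrapped_deg[lam$family == "A"], c(0, 2))
  expect_equal(lam$unwrapped_deg[lam$family == "B"], c(88, 91))

  lam2 <- assign_families_and_unwrap(segment_lamellae(mk_profile(c(85, 175, 95, 5))))
  expect_equal(lam2$family, c("A", "B", "A", "B"))
  expect_equal(lam2$unwrapped_deg[lam2$family == "A"], c(85, 95))
  expect_equal(lam2$unwrapped_deg[lam2$family == "B"], c(175, 185))  # across wrap

  alt <- assign_families_and_unwrap(segment_lamellae(mk_profile(rep(c(0, 90), 6))))
  expect_equal(unique(alt$unwrapped_deg[alt$family == "A"]), 0)
  expect_equal(unique(alt$unwrapped_deg[alt$family == "B"]), 90)
})

test_that("orthogonality is the mean adjacent-pair axial angle", {
  lam <- assign_families_and_unwrap(segment_lamellae(mk_profile(c(0, 90, 3, 93))))
  o <- orthogonality_stats(lam)
  expect_equal(o$pairs, c(90, 87, 90))
  expect_equal(o$orthogonality_deg, 89)

  perfect <- segment_lamellae(mk_profile(rep(c(0, 90), 10)))
  expect_identical(orthogonality_stats(perfect)$orthogonality_deg, 90)

  expect_error(orthogonality_stats(segment_lamellae(mk_profile(5))), "2 lamellae")
})

test_that("angular displacement is the family-averaged unwrapped range", {
  alt <- assign_families_and_unwrap(segment_lamellae(mk_profile(rep(c(0, 90), 10))))
  expect_equal(angular_displacement(alt)$angular_displacement_deg, 0)

  drift <- assign_families_and_unwrap(
    segment_lamellae(mk_profile(c(0, 90, 2, 92, 4, 94))))
  d <- angular_displacement(drift)
  expect_equal(d$angular_displacement_deg, 4)
  expect_equal(d$family_displacements$A, 4)
  expect_equal(d$rotation_sign, 1)

  expect_error(angular_displacement(segment_lamellae(mk_profile(c(0, 90)))),
               "family tracks")
})

test_that("displacement is invariant to global axis offset and depth reversal", {
  set.seed(23)
  for (k in 1:6) {
    n <- 30
    drift <- cumsum(c(0, runif(n - 1, 0, 6)))
    axes <- ifelse(seq_len(n) %% 2 == 1, 0, 90) + drift + rnorm(n, sd = 0.5)
    disp_of <- function(a) {
      lam <- assign_families_and_unwrap(segment_lamellae(mk_profile(a %% 180)))
      angular_displacement(lam)$angular_displacement_deg
    }
    d0 <- disp_of(axes)
    expect_equal(disp_of(axes + 37.3), d0, tolerance = 1e-8)
    expect_equal(disp_of(rev(axes)), d0, tolerance = 1e-8)
    lam <- assign_families_and_unwrap(segment_lamellae(mk_profile(axes %% 180)))
    o <- orthogonality_stats(lam)$orthogonality_deg
    expect_true(o >= 0 && o <= 90)
  }
})

test_that("rotated zone locates the drifting depth range", {
  # no drift anywhere
  flat <- assign_families_and_unwrap(segment_lamellae(mk_profile(rep(c(0, 90), 10))))
  rz <- rotated_zone(flat)
  expect_equal(rz$rotated_fraction_pct, 0)
  expect_null(rz$rotated_span_um)

  # constant drift across the whole depth: 5 deg per lamella, 2 planes each
  n <- 40
  axes <- ifelse(seq_len(n) %% 2 == 1, 0, 90) + 5 * (seq_len(n) - 1)
  prof <- mk_profile(rep(axes %% 180, each = 2))
  lam <- assign_families_and_unwrap(segment_lamellae(prof))
  rz2 <- rotated_zone(lam)
  expect_equal(rz2$rotated_fraction_pct, 100)

  # drift confined to the anterior 70% of a 500 um stack
  sched <- drift_schedule(n_lamellae = 50L, planes_per_lamella = 5L,
                          displacement_deg = 100, zone_lamellae = c(1L, 35L))
  prof3 <- mk_profile(rep(sched$lamellae$axis_deg, each = 5))
  lam3 <- assign_families_and_unwrap(segment_lamellae(prof3))
  rz3 <- rotated_zone(lam3)
  expect_equal((sched$n_planes - 1) * 2, 498)
  expect_lt(abs(rz3$rotated_fraction_pct - 70), 5)
})

test_that("specimen aggregation reports mean and standard error", {
  ms <- lapply(c(90, 88, 86), function(v)
    list(orthogonality_deg = v, angular_displacement_deg = 100,
         rotated_fraction_pct = 70, n_lamellae = 50))
  agg <- aggregate_specimens(ms)
  o <- agg[agg$metric == "orthogonality_deg", ]
  expect_equal(o$mean, 88)
  expect_equal(o$se, 2 / sqrt(3))
  expect_equal(agg[agg$metric == "angular_displacement_deg", "se"], 0)

  one <- aggregate_specimens(ms[1])
  expect_true(is.na(one$se[1]))
  expect_equal(one$mean[1], 90)
})
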