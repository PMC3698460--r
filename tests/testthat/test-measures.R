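test_that("area is the foreground pixel count", {
  expect_equal(measure_area(rect_mask(10, 4)), 40)
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(measure_area(single), 1)
  expect_error(measure_area(matrix(FALSE, 4, 4)), class = "EmptyScribble")
})

test_that("rendered straight segment has stadium area", {
  traj <- stroke_trajectory(1, 100, angle_deg = 0, seed = 1)
  m <- binarize(render_trajectory(traj, 5), threshold = 128)
  stadium <- 100 * 5 + pi * 2.5^2  # 519.6
  expect_lt(abs(measure_area(m) - stadium) / stadium, 0.05)
})

test_that("thickness is recovered from ribbons, rings and trajectories", {
  expect_equal(estimate_thickness(rect_mask(100, 5)), 5, tolerance = 1 / 5)
  expect_equal(estimate_thickness(annulus_mask(30, 2)), 2, tolerance = 1 / 2)
  # rendered bars at several orientations, t in {2, 5, 9}, within +/-15%
  for (ang in c(0, 20, 35, 60, 90)) {
    for (t in c(2, 5, 9)) {
      traj <- stroke_trajectory(1, 100, angle_deg = ang, seed = 1)
      m <- binarize(render_trajectory(traj, t), threshold = 128)
      expect_lt(abs(estimate_thickness(m) - t) / t, 0.15 + 1e-9,
                label = sprintf("thickness error, angle %d pen %d", ang, t))
    }
  }
})

test_that("a filled blob collapses to its radius and is flagged", {
  d <- disk_mask(20)
  expect_warning(t <- estimate_thickness(d, ls_min = 20), class = "BlobWarning")
  expect_equal(t, 20, tolerance = 0.1)
})

test_that("Feret profile matches symmetry and footprint conventions", {
  p <- feret_profile(disk_mask(40))
  expect_true(all(abs(p$diameters - 40) <= 1))
  expect_lt(p$ls_max - p$ls_min, 1)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_true(all(feret_profile(single)$diameters == 1))
})

test_that("Feret profile agrees with the brute-force rotating projection", {
  # the worked rectangle first: min ~ short side, max ~ centre diagonal + 1
  rect <- rect_mask(10, 4)
  p <- feret_profile(rect, angular_step = 0.5)
  o <- feret_oracle(rect, step = 0.5)
  expect_equal(p$ls_min, o$ls_min, tolerance = 1e-9)
  expect_equal(p$ls_max, o$ls_max, tolerance = 1e-9)
  expect_equal(p$ls_min, 4, tolerance = 0.3)
  expect_equal(p$ls_max, sqrt(116), tolerance = 0.5)
  # both diagonals of a symmetric rectangle attain the maximum
  diag_ang <- atan2(3, 9) * 180 / pi
  dev <- min(abs(p$theta_max - diag_ang), abs(180 - p$theta_max - diag_ang))
  expect_lt(dev, 1.5)

  set.seed(21)
  for (i in 1:8) {
    m <- random_mask(40L)
    p <- feret_profile(m, angular_step = 1)
    o <- feret_oracle(m, step = 0.5)
    expect_lt(abs(p$ls_max - o$ls_max), 1)
    expect_lt(abs(p$ls_min - o$ls_min), 1)
  }
})

test_that("rotating a mask by 90 degrees preserves the caliper extrema", {
  set.seed(31)
  for (i in 1:5) {
    m <- random_mask(36L)
    p0 <- feret_profile(m, angular_step = 0.5)
    p1 <- feret_profile(rot90_mask(m), angular_step = 0.5)
    expect_lt(abs(p0$ls_max - p1$ls_max), 1.5)
    expect_lt(abs(p0$ls_min - p1$ls_min), 1.5)
    # the whole caliper profile shifts by 90 degrees (mod 180); comparing
    # profiles avoids argmax ties at symmetric shapes
    n <- length(p0$angles)
    shifted <- c(p1$diameters[(n / 2 + 1):n], p1$diameters[1:(n / 2)])
    expect_lt(max(abs(p0$diameters - shifted)), 1.5)
  }
})
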