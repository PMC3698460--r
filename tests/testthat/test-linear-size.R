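test_that("well-aligned parallel strokes trigger rule I along the stroke axis", {
  traj <- stroke_trajectory(8, 60, drift_per_stroke = 6, angle_deg = 30,
                            length_jitter = 0.05, angle_jitter = 4, seed = 5)
  m <- binarize(render_trajectory(traj, 3), threshold = 128)
  meas <- measure_scribble(m, composition = "strokes")
  expect_equal(meas$rule_id, "I_STROKE_ALIGNED")
  dev <- abs(((meas$direction_deg - 30 + 90) %% 180) - 90)
  expect_lt(dev, 10)
  # LS along the stroke axis ~ stroke length + pen
  expect_equal(meas$linear_size_LS, 63, tolerance = 0.15)
})

test_that("elongated non-aligned masks trigger rule II orthogonal to the major axis", {
  # a drifting loop chain is elongated once drift * (N-1) >> diameter
  traj <- loop_trajectory(15, 40, drift_per_loop = 8, seed = 6)
  m <- binarize(render_trajectory(traj, 2), threshold = 128)
  prof <- feret_profile(m)
  expect_gt(prof$ls_max, 2 * prof$ls_min)
  meas <- measure_scribble(m, composition = "loops")
  expect_equal(meas$rule_id, "II_ELONGATED")
  expect_equal(meas$direction_deg, (prof$theta_max + 90) %% 180)
  # orthogonal diameter ~ loop diameter + pen, not the chain length
  expect_lt(meas$linear_size_LS, prof$ls_max / 2)
})

test_that("compact masks fall through to rule III, the extrema average", {
  m <- disk_mask(46)
  prof <- feret_profile(m)
  sel <- select_linear_size(m, "loops", prof, thickness = 2)
  expect_equal(sel$rule_id, "III_AVERAGE")
  expect_identical(sel$linear_size, (prof$ls_max + prof$ls_min) / 2)
  expect_true(is.na(sel$direction_deg))
})

test_that("elongation uses a strict more-than-twice test", {
  prof <- structure(list(angles = c(0, 90), diameters = c(80, 40),
                         ls_max = 80, ls_min = 40, theta_max = 0),
                    class = "feret_profile")
  sel <- select_linear_size(rect_mask(30, 10), "loops", prof, thickness = 2)
  expect_equal(sel$rule_id, "III_AVERAGE")  # exactly twice is NOT elongated
  expect_equal(sel$linear_size, 60)
})

test_that("rule selection is deterministic and ordered", {
  traj <- stroke_trajectory(8, 60, drift_per_stroke = 6, angle_deg = 30,
                            seed = 5)
  m <- binarize(render_trajectory(traj, 3), threshold = 128)
  prof <- feret_profile(m)
  a <- select_linear_size(m, "strokes", prof, 3)
  b <- select_linear_size(m, "strokes", prof, 3)
  expect_identical(a, b)
  # same mask relabelled as loops can never use rule I
  l <- select_linear_size(m, "loops", prof, 3)
  expect_true(l$rule_id %in% c("II_ELONGATED", "III_AVERAGE"))
})

test_that("an explicit direction override wins and is measured there", {
  m <- rect_mask(30, 10)
  prof <- feret_profile(m)
  sel <- select_linear_size(m, "strokes", prof, 2, direction_deg = 90)
  expect_equal(sel$rule_id, "I_STROKE_ALIGNED")
  expect_equal(sel$direction_deg, 90)
  expect_equal(sel$linear_size, 10, tolerance = 0.05)
})
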