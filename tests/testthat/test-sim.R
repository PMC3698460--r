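test_that("stroke trajectories carry exact ground truth", {
  tr <- stroke_trajectory(1, 50, seed = 4)
  expect_equal(tr$ground_truth$n_elements, 1)
  expect_equal(tr$ground_truth$total_length_L, 50)
  expect_equal(tr$ground_truth$mean_element_length_l, 50)
  expect_equal(nrow(tr$points), 2)

  tr <- stroke_trajectory(10, 60, drift_per_stroke = 6, seed = 4)
  L <- tr$ground_truth$total_length_L
  expect_gte(L, 600)
  expect_lte(L, 600 + 10 * 6)
  expect_equal(length(tr$element_breaks) + 1, 10)

  a <- stroke_trajectory(7, 55, drift_per_stroke = 5, length_jitter = 0.2,
                         angle_jitter = 10, seed = 123)
  b <- stroke_trajectory(7, 55, drift_per_stroke = 5, length_jitter = 0.2,
                         angle_jitter = 10, seed = 123)
  expect_identical(a, b)

  expect_error(stroke_trajectory(0, 50), class = "InvalidParams")
  expect_error(stroke_trajectory(3, -2), class = "InvalidParams")
})

test_that("loop trajectories converge to pi * d per loop", {
  tr <- loop_trajectory(1, 50, points_per_loop = 360, seed = 4)
  expect_lt(abs(tr$ground_truth$total_length_L - pi * 50) / (pi * 50), 0.001)

  tr5 <- loop_trajectory(5, 40, drift_per_loop = 8, seed = 4)
  expect_equal(tr5$ground_truth$n_elements, 5)
  m <- binarize(render_trajectory(tr5, 2), threshold = 128)
  holes <- EBImage::fillHull(m * 1L) == 1L & !m
  expect_gt(sum(holes), 0)

  a <- loop_trajectory(4, 40, diameter_jitter = 0.2, seed = 42)
  b <- loop_trajectory(4, 40, diameter_jitter = 0.2, seed = 42)
  expect_identical(a, b)
})

test_that("ground truth is internally consistent", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(1:22, 1)
    tr <- if (i %% 2) {
      stroke_trajectory(n, 60, drift_per_stroke = 6, length_jitter = 0.1,
                        angle_jitter = 8, seed = i)
    } else {
      loop_trajectory(n, 40, drift_per_loop = 8, diameter_jitter = 0.1,
                      seed = i)
    }
    gt <- tr$ground_truth
    expect_equal(gt$n_elements, n)
    expect_equal(gt$mean_element_length_l * gt$n_elements,
                 gt$total_length_L, tolerance = 1e-9)
  }
})

test_that("rendering stamps a round pen of the right footprint", {
  dot <- stroke_trajectory(1, 1e-9, seed = 1)  # effectively a point
  dot$points <- dot$points[1, , drop = FALSE]
  m <- binarize(render_trajectory(dot, 4), threshold = 128)
  expect_lt(abs(measure_area(m) - pi * 4) / (pi * 4), 0.15)

  seg <- stroke_trajectory(1, 100, angle_deg = 0, seed = 1)
  m2 <- binarize(render_trajectory(seg, 5), threshold = 128)
  expect_lt(abs(measure_area(m2) - 519.6) / 519.6, 0.05)

  expect_error(render_trajectory(seg, 0.5), class = "InvalidParams")
})

test_that("area over thickness under-estimates the true path length", {
  # ink area cannot exceed the swept stadium; overlap only removes ink
  for (sd in 1:3) {
    tr <- stroke_trajectory(12, 60, drift_per_stroke = 6, length_jitter = 0.1,
                            angle_jitter = 8, seed = sd)
    m <- binarize(render_trajectory(tr, 3), threshold = 128)
    expect_lt(measure_area(m) / 3, 1.05 * tr$ground_truth$total_length_L)
  }
})

test_that("the factorial design yields the full manifest deterministically", {
  spec <- design_spec(repetitions = 1, levels = c(1, 6), base_seed = 9)
  d1 <- file.path(tempdir(), "sim-det-1")
  d2 <- file.path(tempdir(), "sim-det-2")
  m1 <- simulate_design(spec, d1)
  m2 <- simulate_design(spec, d2)
  expect_equal(nrow(m1), 2 * 2 * 2 * 1)
  expect_identical(m1$true_L, m2$true_L)
  expect_identical(m1$seed, m2$seed)
  # byte-identical images across runs
  f1 <- file.path(d1, paste0(m1$id[1], ".png"))
  f2 <- file.path(d2, paste0(m2$id[1], ".png"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # default design size: 2 x 2 x 6 x 4
  expect_equal(with(design_spec(), length(pen_thicknesses) * length(kinds) *
                      length(levels) * repetitions), 96)
})

test_that("design specs round-trip through JSON config files", {
  fp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(repetitions = 2, levels = c(1, 3, 6),
                            pen_thicknesses = c(2)), fp, auto_unbox = TRUE)
  spec <- read_design_spec(fp)
  expect_equal(spec$repetitions, 2)
  expect_equal(spec$levels, c(1L, 3L, 6L))
  expect_equal(spec$pen_thicknesses, 2)
  expect_equal(spec$kinds, c("STROKES", "LOOPS"))  # default preserved
})
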