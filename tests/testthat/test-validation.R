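test_that("correlation and OLS helpers match hand-computed values", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)

  expect_equal(fit_line(c(1, 2), c(1, 2)), c(slope = 1, intercept = 0))
  expect_equal(fit_line(c(0, 1), c(1, 3)), c(slope = 2, intercept = 1))
  expect_equal(fit_line(c(1, 2, 3), c(1, 2, 2)),
               c(slope = 0.5, intercept = 2 / 3), tolerance = 1e-12)
})

test_that("degenerate series are rejected", {
  expect_error(pearson_r(c(1, 2), c(1, 2)), class = "DegenerateInput")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "DegenerateInput")
  expect_error(pearson_r(1:3, 1:4), class = "DegenerateInput")
  expect_error(fit_line(c(2, 2, 2), c(1, 2, 3)), class = "DegenerateInput")
})

test_that("under-estimation is the slope complement in percent", {
  expect_equal(underestimation(1), 0)
  expect_equal(underestimation(0.5), 50)
  expect_error(underestimation(Inf), class = "InvalidParams")
  # printed to one decimal, a slope of 0.2743 reads 72.6%
  expect_equal(round(underestimation(0.2743), 1), 72.6)
})

test_that("a reduced design produces a coherent validation report", {
  spec <- design_spec(repetitions = 1, levels = c(1, 6, 15), base_seed = 3)
  man <- simulate_design(spec, file.path(tempdir(), "val-small"))
  rep <- validate_design(man)
  expect_s3_class(rep, "spi_validation")
  expect_equal(rep$n_items, 12)
  expect_equal(rep$n_failed, 0)
  expect_equal(rep$underestimation_pct, 100 * (1 - rep$slope))
  expect_equal(unname(coef(rep)), c(rep$intercept, rep$slope))
  expect_gt(rep$r_spi, 0)
  # report serialization round-trips
  jp <- tempfile(fileext = ".json")
  write_validation_report(rep, jp)
  out <- jsonlite::read_json(jp)
  expect_equal(out$r_spi, rep$r_spi, tolerance = 1e-12)
  expect_equal(out$n_items, 12L)
})

test_that("missing image files are excluded and counted, not fatal", {
  spec <- design_spec(repetitions = 1, levels = c(1, 6, 15),
                      kinds = "STROKES", base_seed = 3)
  man <- simulate_design(spec, file.path(tempdir(), "val-missing"))
  man$filepath[2] <- file.path(tempdir(), "nope.png")
  man2 <- rbind(man, man[c(1, 3, 4), ])  # keep >= 3 scorable with variance
  rep <- validate_design(man2)
  expect_equal(rep$n_failed, 1)
  expect_equal(rep$n_items, nrow(man2) - 1)
})

test_that("single-element scribbles score near zero on average", {
  spec <- design_spec(levels = 1, base_seed = 5)  # the 4 N = 1 cells
  man <- simulate_design(spec, file.path(tempdir(), "val-n1"))
  out <- vapply(seq_len(nrow(man)), function(i) {
    score_scribble(man$filepath[i],
                   composition = tolower(man$kind[i]))$spi
  }, numeric(1))
  expect_lt(mean(out), 0.2)
})

test_that("identical true N across items makes correlations undefined", {
  spec <- design_spec(levels = 6, repetitions = 2, kinds = "STROKES",
                      pen_thicknesses = 2, base_seed = 8)
  man <- simulate_design(spec, file.path(tempdir(), "val-const"))
  expect_error(validate_design(man), class = "DegenerateInput")
})
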