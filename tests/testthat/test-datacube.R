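test_that("cube and design constructors enforce their invariants", {
  x <- array(runif(5 * 4 * 2), c(5, 4, 2))
  cube <- data_cube(x, 1:5, seq(200, 206, 2), c("a", "b"))
  expect_s3_class(cube, "DataCube")
  expect_identical(dim(cube), c(5L, 4L, 2L))

  expect_error(data_cube(x, 1:4, seq(200, 206, 2), c("a", "b")),
               "do not match")
  expect_error(data_cube(x, c(1, 3, 2, 4, 5), seq(200, 206, 2), c("a", "b")),
               "strictly increasing")
  expect_error(data_cube(x, 1:5, seq(200, 206, 2), c("a", "a")), "unique")
  x[1] <- NA
  expect_error(data_cube(x, 1:5, seq(200, 206, 2), c("a", "b")), "finite")
  # an empty sample mode is rejected outright
  expect_error(data_cube(array(0, c(5, 4, 0)), 1:5, seq(200, 206, 2),
                         character()), "at least one sample")

  expect_error(
    calibration_design(c("a", "b"), c("calibration", "mystery"),
                       matrix(1, 2, 1)),
    "unknown role")
  expect_error(
    calibration_design(c("a", "b"), c("calibration", "calibration"),
                       matrix(c(1, NA), 2, 1)),
    "complete concentration row")
  expect_error(
    calibration_design(c("a", "b"), c("calibration", "calibration"),
                       matrix(c(1, -2), 2, 1)),
    "nonnegative")
})

test_that("save/load round trip preserves values, axes, roles and levels", {
  sim <- coarse_paperlike(seed = 2, noise_sd = 0.005, n_time = 30,
                          n_wavelength = 20)
  td <- withr::local_tempdir()
  paths <- save_cube(sim$cube, sim$design, td)
  # one matrix file per sample plus the metadata file
  expect_length(paths, length(sim$cube$sample_ids) + 1L)
  ld <- load_cube(td)
  expect_lt(max(abs(ld$cube$values - sim$cube$values)), 1e-8)
  expect_equal(ld$cube$time_axis, sim$cube$time_axis, tolerance = 1e-12)
  expect_equal(ld$cube$wavelength_axis, sim$cube$wavelength_axis,
               tolerance = 1e-12)
  expect_identical(ld$design$roles, sim$design$roles)
  expect_equal(ld$design$conc, sim$design$conc, tolerance = 1e-12)
})

test_that("load_cube rejects malformed directories atomically", {
  sim <- coarse_paperlike(seed = 3, n_time = 12, n_wavelength = 8)
  td <- withr::local_tempdir()
  save_cube(sim$cube, sim$design, td)

  expect_error(load_cube(file.path(td, "no-such-dir")), "not found")

  f <- file.path(td, "cal01.csv")
  lines <- readLines(f)
  writeLines(c(lines[-1], "1,2,3"), f)            # wrong row length
  expect_error(load_cube(td), "shape mismatch|malformed")

  writeLines(gsub("^[^,]*", "oops", lines), f)    # non-numeric cell
  expect_error(load_cube(td), "[Nn]on-numeric|malformed")

  file.remove(f)
  expect_error(load_cube(td), "missing sample file")
})

test_that("blank subtraction removes the element-wise mean blank", {
  x <- array(runif(6 * 5 * 3, 1, 2), c(6, 5, 3))
  x[, , 2] <- x[, , 1]
  x[, , 3] <- x[, , 1]
  cube <- data_cube(x, 1:6, seq(200, 208, 2), c("s", "b1", "b2"))
  # every slab equals the blank: output is identically zero
  out <- subtract_blank(cube, c("b1", "b2"))
  expect_identical(out$sample_ids, "s")
  expect_lt(max(abs(out$values)), 1e-12)

  # two distinct blanks: offset is their element-wise mean
  x[, , 3] <- x[, , 3] + 1
  cube <- data_cube(x, 1:6, seq(200, 208, 2), c("s", "b1", "b2"))
  out <- subtract_blank(cube, c("b1", "b2"))
  expect_equal(out$values[, , 1],
               x[, , 1] - (x[, , 2] + x[, , 3]) / 2, tolerance = 1e-12)

  expect_error(subtract_blank(cube, "nope"), "unknown blank")
  expect_error(subtract_blank(cube, c("s", "b1", "b2")), "all samples")
})

test_that("blank subtraction recovers the baseline-free signal", {
  beta <- 0.05
  simb <- simulate_cube(simulation_config(
    default_components(), n_calibration = 10, n_prediction = 6, n_blank = 3,
    time_axis = seq(0, 5, length.out = 76),
    wavelength_axis = seq(200, 380, length.out = 46),
    noise_sd = 0.002, baseline_offset = beta, seed = 4))
  blanks <- simb$cube$sample_ids[simb$design$roles == "blank"]
  out <- subtract_blank(simb$cube, blanks)
  resid <- out$values - simb$truth$clean[, , simb$design$roles != "blank"]
  # residual is pure noise: sd near sqrt(1 + 1/3) times the per-point sd
  expect_lt(max(abs(resid)), 6 * simb$truth$noise_sd_abs * sqrt(4 / 3))
  expect_lt(abs(sd(resid) / (simb$truth$noise_sd_abs * sqrt(4 / 3)) - 1),
            0.05)
})

test_that("region selection crops closed windows without reordering", {
  sim <- coarse_paperlike(seed = 5, n_time = 151, n_wavelength = 20)
  cube <- sim$cube
  full <- select_region(cube, range(cube$time_axis),
                        range(cube$wavelength_axis))
  expect_equal(full$values, cube$values)

  # 1/30-min grid from 0: the closed window [1, 2] keeps 31 points
  cropped <- select_region(cube, time_window = c(1, 2))
  expect_length(cropped$time_axis, 31L)
  expect_identical(cropped$time_axis, cube$time_axis[31:61])
  expect_false(is.unsorted(cropped$time_axis, strictly = TRUE))

  expect_error(select_region(cube, time_window = c(90, 99)),
               "does not intersect")
})
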