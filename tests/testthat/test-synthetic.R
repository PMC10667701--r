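test_that("degenerate one-mode mixture draws every tube at the mode angle", {
  net <- make_tube_network_image(tube_network_spec(
    data.frame(angle_deg = 30, weight = 1), n_tubes = 25, seed = 4))
  expect_true(all(net$drawn_angles_deg == 30))
})

test_that("balanced two-mode mixture splits drawn angles roughly evenly", {
  net <- make_tube_network_image(tube_network_spec(
    data.frame(angle_deg = c(20, 80), weight = c(0.5, 0.5)),
    n_tubes = 200, seed = 11))
  counts <- table(net$drawn_angles_deg)
  expect_setequal(as.numeric(names(counts)), c(20, 80))
  expect_true(all(counts >= 80))
})

test_that("an empty noiseless network is a constant background image", {
  net <- make_tube_network_image(tube_network_spec(
    data.frame(angle_deg = 0, weight = 1), n_tubes = 0,
    noise_sd = 0, background_level = 177, seed = 1))
  expect_true(all(net$image == 177))
  expect_length(net$drawn_angles_deg, 0)
})

test_that("generators are bit-reproducible and bounded in [0, 255]", {
  spec <- tube_network_spec(data.frame(angle_deg = c(10, 100), weight = c(2, 1)),
                            n_tubes = 60, noise_sd = 8, seed = 99)
  a <- make_tube_network_image(spec)
  b <- make_tube_network_image(spec)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$drawn_angles_deg, b$drawn_angles_deg)
  for (s in 1:5) {
    img <- make_tube_network_image(tube_network_spec(
      data.frame(angle_deg = 45, weight = 1), tube_darkness = 255,
      background_level = 30, noise_sd = 20, seed = s))$image
    expect_gte(min(img), 0)
    expect_lte(max(img), 255)
  }
})

test_that("crossing movies carry their construction-forced ground truth", {
  mv <- make_crossing_movie(crossing_movie_spec(0.18, seed = 2))
  expect_equal(mv$te_min, 100)   # 18 mm / 0.18 mm per min
  expect_equal(mv$t0_min, 0)
  # sheet footprint covers the full 18 x 18 bridge at completion
  sheet <- make_crossing_movie(crossing_movie_spec(0.3, footprint = "sheet",
                                                   noise_sd = 0, seed = 1))
  expect_equal(sheet$final_area_mm2, 324)
  # string footprint area is the rendered path pixel count times pixel area
  str <- make_crossing_movie(crossing_movie_spec(0.18, footprint = "string",
                                                 seed = 3))
  expect_equal(str$final_area_mm2, sum(str$final_mask) * 0.0625^2)
  expect_error(crossing_movie_spec(-1), "positive")
  expect_error(crossing_movie_spec(0.17), "integer number of frames")
})

test_that("oscillation movies sample the programmed sinusoid exactly", {
  mv <- make_oscillation_movie(oscillation_movie_spec(
    period_field = 100, amplitude = 40, noise_sd = 0, seed = 1))
  expect_equal(n_frames(mv$stack), 121)   # 600 s / 5 s + 1, inclusive of t = 0
  g <- grid_mean_series(mv$stack)
  t <- (0:120) * 5
  expected <- 150 + 40 * sin(2 * pi * t / 100)
  expect_equal(unname(g$series[1, ]), expected, tolerance = 1e-10)
  # amplitude 0 gives a constant movie
  flat <- make_oscillation_movie(oscillation_movie_spec(
    period_field = 100, amplitude = 0, noise_sd = 0, seed = 1))
  expect_true(all(vapply(flat$stack$frames, function(f) all(f == 150), logical(1))))
  expect_error(oscillation_movie_spec(duration_s = 601), "divisible")
  expect_error(oscillation_movie_spec(period_field = -5), "positive")
})

test_that("study tables honour configured means, effects and the seed", {
  # zero effects, zero dispersion: every value equals its baseline
  tab0 <- make_study_table(study_table_spec(
    n_per_cell = 4, dispersion = list(area = 0, speed = 0, omega = 0), seed = 1))
  expect_true(all(tab0$area == 30))
  expect_true(all(tab0$speed == 0.15))
  # per-day additive drift is recovered by the cell means
  drift <- c(0, 10, 20, 30)
  tab <- make_study_table(study_table_spec(
    n_per_cell = 200, day_effects = list(quinine = list(area = drift)),
    dispersion = list(area = 5, speed = 0, omega = 0), seed = 5))
  for (d in 1:4) {
    m <- mean(tab$area[tab$condition == "quinine" & tab$day == d])
    expect_equal(m, 30 + drift[d], tolerance = 0.05)
  }
  # determinism under a fixed seed
  spec <- study_table_spec(seed = 77)
  expect_identical(make_study_table(spec), make_study_table(spec))
  # lognormal with zero dispersion also sits exactly on the baseline
  lg <- make_study_table(study_table_spec(
    n_per_cell = 3, family = "lognormal",
    dispersion = list(area = 0, speed = 0, omega = 0), seed = 2))
  expect_true(all(lg$omega == 0.06))
})

test_that("image stacks round-trip through TIFF with their sidecar", {
  mv <- make_oscillation_movie(oscillation_movie_spec(
    period_field = 100, grid_blocks = 4, block_px = 5, duration_s = 50, seed = 1))
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_image_stack(mv$stack, path, ground_truth = list(period_s = 100))
  rt <- read_image_stack(path)
  expect_equal(n_frames(rt), n_frames(mv$stack))
  expect_equal(rt$frame_interval, 5)
  expect_equal(rt$interval_unit, "s")
  expect_equal(rt$frames[[3]], round(mv$stack$frames[[3]]), tolerance = 0.51)
})
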