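test_that("constant images yield an empty, flagged distribution", {
  img <- gray_image(matrix(128, 128, 128), 0.0625)
  d <- power_spectrum_angles(img)
  expect_true(d$empty)
  expect_error(characteristic_angle(d), "empty")
  expect_error(power_spectrum_angles(matrix(0, 100, 120)), "square")
  expect_error(power_spectrum_angles(matrix(0, 32, 32)), "64")
})

test_that("a pure grating concentrates spectral weight at the normal angle", {
  # ridges run vertically (tube angle 90), wave vector along columns:
  # spectral angle 0.  The wavelength divides the image side, so the DFT is
  # exact impulses and no taper is needed.
  g <- make_grating(128, tube_deg = 90, wl = 16)
  d <- power_spectrum_angles(g, window = "none")
  near0 <- angle_deviation(d$angles_deg, 0) <= 5
  expect_gte(sum(d$weights[near0]) / sum(d$weights), 0.9)
  # the same grating rotated 45 degrees moves the dominant angle to 45
  g45 <- make_grating(128, tube_deg = 135, wl = 12)
  d45 <- power_spectrum_angles(g45)
  ca <- characteristic_angle(d45)
  expect_lt(angle_deviation(ca$peak_angles_deg[1], 45), 5)
})

test_that("the density mode matches the sample it was drawn from", {
  # all weight at one angle
  d1 <- angle_distribution(rep(72, 50), rep(1, 50))
  ca1 <- characteristic_angle(d1, bw = 2)
  expect_lt(angle_deviation(ca1$peak_angles_deg[1], 72), 0.5)
  # weighted sample around 30: mode within 2 degrees
  set.seed(21)
  a <- fold180(rnorm(400, 30, 4))
  w <- runif(400, 0.5, 1.5)
  ca2 <- characteristic_angle(angle_distribution(a, w))
  expect_lt(angle_deviation(ca2$peak_angles_deg[1], 30), 2)
})

test_that("bimodal distributions match a brute-force periodic KDE oracle", {
  set.seed(8)
  a <- fold180(c(rnorm(300, 20, 3), rnorm(300, 80, 3)))
  w <- rep(1, 600)
  ca <- characteristic_angle(angle_distribution(a, w), bw = 3)
  oracle <- brute_kde_peaks(a, w, bw = 3)
  expect_equal(length(ca$peak_angles_deg), length(oracle))
  expect_lt(angle_deviation(ca$peak_angles_deg[1], oracle[1]), 1)
  expect_lt(angle_deviation(ca$peak_angles_deg[2], oracle[2]), 1)
  expect_lt(angle_deviation(ca$peak_angles_deg[1], 20), 3)
  expect_lt(angle_deviation(ca$peak_angles_deg[2], 80), 3)
})

test_that("spectral-to-tube conversion is the quarter-turn map", {
  expect_equal(tube_angle_from_spectral(0), 90)
  expect_equal(tube_angle_from_spectral(90), 0)
  expect_equal(tube_angle_from_spectral(135), 45)
  # involution: applying it twice is the identity on [0, 180)
  for (a in seq(0, 175, 5))
    expect_equal(tube_angle_from_spectral(tube_angle_from_spectral(a)), a)
})

test_that("single-mode networks are recovered on a 15-degree grid", {
  for (th in c(0, 45, 105, 150)) {
    net <- make_tube_network_image(tube_network_spec(
      data.frame(angle_deg = th, weight = 1), seed = 300 + th))
    ca <- characteristic_angle(power_spectrum_angles(net$image))
    est <- tube_angle_from_spectral(ca$peak_angles_deg[1])
    expect_lt(angle_deviation(est, th), 3)
    expect_true(all(ca$peak_angles_deg >= 0 & ca$peak_angles_deg < 180))
  }
})

test_that("generated multi-mode networks show the right number of peaks", {
  cases <- list(one = 40, two = c(20, 75), three = c(10, 70, 130))
  hits <- 0; total <- 0
  for (nm in names(cases)) {
    modes <- cases[[nm]]
    for (s in 1:10) {
      net <- make_tube_network_image(tube_network_spec(
        data.frame(angle_deg = modes, weight = rep(1, length(modes))),
        n_tubes = 30 * length(modes), seed = 17 * s + length(modes)))
      ca <- characteristic_angle(power_spectrum_angles(net$image))
      total <- total + 1
      hits <- hits + (length(ca$peak_angles_deg) == length(modes))
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("the orientation time course tracks state changes over network time", {
  tree <- make_goal_day_stack("tree", n_frames = 4, seed = 5)
  ser <- orientation_time_course(tree$stack, tree$network_times)
  expect_s3_class(ser, "characteristic_angle_series")
  expect_equal(nrow(ser), 4)
  first_peaks <- vapply(ser$peak_angles_deg, `[`, numeric(1), 1)
  expect_true(all(angle_deviation(first_peaks, 20) < 3))

  # a stack transitioning from one mode to two reports two peaks later on
  tr1 <- make_network_state_image("tree", seed = 31)$image
  tr2 <- make_network_state_image("tree", seed = 32)$image
  ms1 <- make_network_state_image("mesh", seed = 33)$image
  ms2 <- make_network_state_image("mesh", seed = 34)$image
  st <- image_stack(list(tr1, tr2, ms1, ms2), 100, "min", 0.0625)
  ser2 <- orientation_time_course(st, c(-300, -200, -100, 0))
  expect_length(ser2$peak_angles_deg[[1]], 1)
  expect_length(ser2$peak_angles_deg[[4]], 2)
  expect_error(orientation_time_course(st, c(-1, 0)), "one time per frame")
})

test_that("final-state pooling returns the day's characteristic angles", {
  tree <- make_goal_day_stack("tree", n_frames = 5, seed = 9)
  ser <- orientation_time_course(tree$stack, tree$network_times)
  fin <- final_state_angles(ser)
  expect_lt(angle_deviation(fin$peak_angles_deg[1], 20), 3)

  mesh <- make_goal_day_stack("mesh", n_frames = 5, seed = 10)
  ser_m <- orientation_time_course(mesh$stack, mesh$network_times)
  fin_m <- final_state_angles(ser_m)
  devs <- sort(angle_deviation(fin_m$peak_angles_deg, 0))
  expect_lt(abs(devs[1] - 20), 3)
  expect_lt(abs(devs[2] - 75), 3)
  expect_error(final_state_angles(ser, window = c(-1000, -900)), "window")
})

test_that("rotating the scene rotates every reported tube angle with it", {
  net <- make_tube_network_image(tube_network_spec(
    data.frame(angle_deg = 30, weight = 1), image_size_px = c(256, 256),
    seed = 77))
  for (phi in c(15, 45, 90)) {
    r <- rotate_crop(net$image, phi)
    ca <- characteristic_angle(power_spectrum_angles(r))
    est <- tube_angle_from_spectral(ca$peak_angles_deg[1])
    expect_lt(angle_deviation(est, 30 + phi), 3)
  }
})
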