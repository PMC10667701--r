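test_that("bridge area is zero for identical frames and exact on known masks", {
  img <- gray_image(matrix(120, 64, 64), 0.0625)
  roi <- bridge_roi(0, 0, 64, 64)
  expect_equal(estimate_bridge_area(img, img, roi), 0)

  # noiseless, unblurred movie: foreground equals the binary footprint mask
  mv <- make_crossing_movie(crossing_movie_spec(0.18, footprint = "string",
                                                blur_sd_px = 0, noise_sd = 0,
                                                seed = 1))
  roi_b <- bridge_roi(0, 0, 288, 288)
  a <- estimate_bridge_area(get_frame(mv$stack, n_frames(mv$stack)),
                            get_frame(mv$stack, 1), roi_b)
  expect_equal(a, sum(mv$final_mask) * 0.0625^2)   # K pixels x (0.0625 mm)^2

  # full-coverage sheet: the whole 18 x 18 mm bridge, 324 mm^2
  sheet <- make_crossing_movie(crossing_movie_spec(0.3, footprint = "sheet",
                                                   blur_sd_px = 0, noise_sd = 0,
                                                   seed = 1))
  # a full-coverage difference image is constant, so an automatic threshold
  # has nothing to separate; the fixed-threshold override applies
  a_sheet <- estimate_bridge_area(get_frame(sheet$stack, n_frames(sheet$stack)),
                                  get_frame(sheet$stack, 1), roi_b,
                                  threshold_policy = 60)
  expect_equal(a_sheet, 324)
})

test_that("area is invariant under joint intensity inversion and scales with pixel size", {
  mv <- make_crossing_movie(crossing_movie_spec(0.18, footprint = "branched",
                                                seed = 6))
  roi <- bridge_roi(0, 0, 288, 288)
  te_f <- get_frame(mv$stack, n_frames(mv$stack))
  t0_f <- get_frame(mv$stack, 1)
  a <- estimate_bridge_area(te_f, t0_f, roi)
  inv_te <- gray_image(255 - unclass(te_f), 0.0625)
  inv_t0 <- gray_image(255 - unclass(t0_f), 0.0625)
  expect_equal(estimate_bridge_area(inv_te, inv_t0, roi), a)
  # doubling the pixel size quadruples the area for the same pixel count
  te2 <- gray_image(unclass(te_f), 0.125)
  t02 <- gray_image(unclass(t0_f), 0.125)
  expect_equal(estimate_bridge_area(te2, t02, roi), 4 * a)
})

test_that("crossing times are recovered within one frame interval", {
  roi <- bridge_roi(0, 0, 288, 288)
  for (fp in c("string", "sheet")) {
    mv <- make_crossing_movie(crossing_movie_spec(0.18, footprint = fp,
                                                  seed = 8))
    st <- detect_crossing_times(mv$stack, roi)
    expect_true(st$crossed)
    expect_lte(abs(st$te_min - mv$te_min), 5)
    sp <- crossing_speed(18, st)
    expect_lte(abs(sp - 0.18), 18 * 5 / mv$te_min^2 + 1e-9)
  }
})

test_that("a movie with no front yields the not-crossed signal", {
  frames <- replicate(5, matrix(150, 64, 64), simplify = FALSE)
  stack <- image_stack(frames, 5, "min", 0.0625)
  st <- detect_crossing_times(stack, bridge_roi(0, 0, 64, 64))
  expect_false(st$crossed)
  expect_true(is.na(st$te_min))
  expect_error(crossing_speed(18, st), "did not cross")
})

test_that("a front already spanning when first visible is degenerate", {
  bg <- matrix(200, 64, 64)
  full <- bg; full[, 30:34] <- 60   # spanning streak present immediately
  stack <- image_stack(c(list(bg), replicate(3, full, simplify = FALSE)),
                       5, "min", 0.0625)
  expect_error(detect_crossing_times(stack, bridge_roi(0, 0, 64, 64)),
               "degenerate")
})

test_that("crossing speed follows bridge_length / (te - t0)", {
  expect_equal(crossing_speed(18, 110), 18 / 110)
  expect_equal(crossing_speed(18, 110), 0.16364, tolerance = 1e-4)
  expect_equal(crossing_speed(18, 285), 0.06316, tolerance = 1e-4)
  expect_error(crossing_speed(18, 0), "exceed")
  expect_error(crossing_speed(18, -5), "exceed")
})

test_that("control normalization is exact on the control group itself", {
  expect_equal(normalize_by_control(c(2, 4), c(1, 3)), c(1, 2))
  set.seed(1)
  ctrl <- rlnorm(12)
  expect_equal(mean(normalize_by_control(ctrl, ctrl)), 1)
  expect_equal(median(normalize_by_control(ctrl, ctrl, "median")), 1)
  expect_error(normalize_by_control(1, numeric(0)), "empty")
  expect_error(normalize_by_control(1, c(0, 0)), "zero")
})
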