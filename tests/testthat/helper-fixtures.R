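# shared fixture builders; everything is generated in code at test time

# sinusoidal grating whose ridges run at math angle `tube_deg` (y up),
# wavelength `wl` px
make_grating <- function(n = 128, tube_deg = 90, wl = 12, level = 128, amp = 60) {
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  x <- cc; y <- n + 1 - rr
  th <- (tube_deg + 90) * pi / 180  # wave vector is normal to the ridges
  phase <- (x * cos(th) + y * sin(th)) * 2 * pi / wl
  gray_image(level + amp * sin(phase), pixel_size_mm = 0.0625)
}

# brute-force weighted periodic KDE on a fine grid; independent of the
# density() path used by characteristic_angle()
brute_kde_peaks <- function(angles, weights, bw, grid_step = 0.25,
                            prominence_frac = 0.25) {
  g <- seq(0, 180 - grid_step, by = grid_step)
  y <- vapply(g, function(a) {
    d <- abs(a - angles) %% 180
    d <- pmin(d, 180 - d)
    sum(weights * exp(-d^2 / (2 * bw^2)))
  }, numeric(1))
  n <- length(y)
  left <- c(y[n], y[-n]); right <- c(y[-1], y[1])
  idx <- which(y > left & y >= right & y >= prominence_frac * max(y))
  g[idx][order(-y[idx])]
}

# run the image pipeline for a 4-day state sequence and return the type
cohort_daily_type <- function(states4, seed) {
  labs <- vapply(seq_along(states4), function(day) {
    ds <- make_goal_day_stack(states4[day], seed = seed * 101L + day)
    classify_day_from_images(ds$stack, ds$network_times)$label
  }, character(1))
  classify_daily_type(labs)
}
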