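#' Nyquist frequency and half-Nyquist noise cutoff
#'
#' At a sampling interval of `frame_interval_s` seconds the Nyquist frequency
#' is `1 / (2 * frame_interval_s)` Hz (0.1 Hz at the standard 5-s interval).
#' Blocks whose angular frequency exceeds half the Nyquist frequency,
#' `2 * pi * f_n / 2` rad/s, are discarded as noise — a stricter threshold
#' than the usual Nyquist bound.
#'
#' @param frame_interval_s sampling interval in seconds.
#' @return frequency in Hz (`nyquist_frequency_hz`) or the omission cutoff in
#'   rad/s (`omega_noise_cutoff`).
#' @export
nyquist_frequency_hz <- function(frame_interval_s) 1 / (2 * frame_interval_s)

#' @rdname nyquist_frequency_hz
#' @export
omega_noise_cutoff <- function(frame_interval_s) {
  2 * pi * nyquist_frequency_hz(frame_interval_s) / 2
}

#' Block-averaged intensity time series over the start-block ROI
#'
#' The 320 x 320 px analysis region is divided into 10 x 10 px blocks (a
#' 32 x 32 grid, 1024 blocks) and the transmitted-light intensity is averaged
#' per block and frame.
#'
#' @param stack an [image_stack()] timed in seconds.
#' @param roi_origin 0-based `c(row, col)` of the ROI top-left corner.
#' @param roi_px ROI side in px (default 320); must be divisible by
#'   `block_px`.
#' @param block_px block edge (default 10).
#' @return a `grid_time_series`: list with `series` (blocks x frames matrix),
#'   `block_row`, `block_col` (1-based grid coordinates per row of `series`),
#'   `frame_interval_s`, `grid_blocks`.
#' @export
grid_mean_series <- function(stack, roi_origin = c(0, 0), roi_px = 320,
                             block_px = 10) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$interval_unit != "s")
    stop("oscillation analysis expects a stack timed in seconds")
  if (roi_px %% block_px != 0)
    stop("ROI side must be divisible by the block size")
  d <- dim(stack$frames[[1]])
  if (roi_origin[1] + roi_px > d[1] || roi_origin[2] + roi_px > d[2])
    stop("ROI lies outside the image")
  g <- roi_px %/% block_px
  # block-mean operator: t(B) %*% img %*% B averages each block
  B <- matrix(0, roi_px, g)
  B[cbind(seq_len(roi_px), rep(seq_len(g), each = block_px))] <- 1 / block_px
  rows <- roi_origin[1] + seq_len(roi_px)
  cols <- roi_origin[2] + seq_len(roi_px)
  nf <- n_frames(stack)
  series <- matrix(NA_real_, g * g, nf)
  for (i in seq_len(nf)) {
    bm <- t(B) %*% stack$frames[[i]][rows, cols] %*% B
    series[, i] <- as.vector(bm)   # column-major: block_row fastest
  }
  structure(list(series = series,
                 block_row = rep(seq_len(g), times = g),
                 block_col = rep(seq_len(g), each = g),
                 frame_interval_s = stack$frame_interval, grid_blocks = g),
            class = "grid_time_series")
}

#' Smooth a time series by locally-weighted polynomial regression
#'
#' Wraps `stats::lowess`.  The default span (fraction 0.1 of the series, about
#' 60 s of a 10-min recording) preserves oscillations in the 60-200 s range
#' while removing frame-to-frame noise.
#'
#' @param series numeric vector, length >= 10.
#' @param f lowess span as a fraction of the series length (default 0.1).
#' @param iter lowess robustness iterations (default 2).
#' @return smoothed series of the same length.
#' @export
smooth_series <- function(series, f = 0.1, iter = 2) {
  if (length(series) < 10) stop("series too short to smooth")
  stats::lowess(seq_along(series), series, f = f, iter = iter)$y
}

# strict local maxima with plateau runs collapsed to their left edge
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  # collapse exact plateaus: a peak sample is > next distinct value on both sides
  idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (y[i] > y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[i]) j <- j + 1   # plateau
      if (j < n && y[j + 1] < y[i]) idx <- c(idx, i)  # left edge of plateau
      i <- j + 1
    } else i <- i + 1
  }
  idx
}

# topographic prominence: height above the higher of the two bounding valleys
peak_prominence <- function(y, idx) {
  vapply(idx, function(p) {
    l <- p; minl <- y[p]
    while (l > 1 && y[l] <= y[p]) { l <- l - 1; minl <- min(minl, y[l]) }
    r <- p; minr <- y[p]
    while (r < length(y) && y[r] <= y[p]) { r <- r + 1; minr <- min(minr, y[r]) }
    y[p] - max(minl, minr)
  }, numeric(1))
}

#' Oscillation periods as gaps between successive peaks
#'
#' Peaks are strict local maxima of the (smoothed) series with topographic
#' prominence at least `prominence_frac` of the series' interquartile range;
#' plateau peaks take their left edge.  Periods are the times between
#' successive peaks, in seconds.
#'
#' @param series numeric vector (typically from [smooth_series()]).
#' @param frame_interval_s sampling interval in seconds.
#' @param prominence_frac prominence threshold as a fraction of the IQR
#'   (default 0.1).
#' @return numeric vector of periods in seconds; empty when fewer than two
#'   peaks are found.
#' @export
peak_periods <- function(series, frame_interval_s, prominence_frac = 0.1) {
  idx <- local_maxima(series)
  if (length(idx) == 0) return(numeric(0))
  iqr <- stats::IQR(series)
  if (iqr > 0) {
    prom <- peak_prominence(series, idx)
    idx <- idx[prom >= prominence_frac * iqr]
  }
  if (length(idx) < 2) return(numeric(0))
  diff(idx) * frame_interval_s
}

#' Representative angular frequency of one block
#'
#' The block period T is the mode of the period histogram (bin width =
#' the frame interval; ties break toward the longer period, conservative
#' against the noise cutoff) and is converted to angular frequency
#' omega = 2 pi / T.  Blocks whose omega exceeds the half-Nyquist cutoff
#' (T < 20 s at 5-s sampling) are omitted as noise, as are blocks with no
#' measurable peaks.
#'
#' @param periods numeric vector of peak-to-peak periods (s), possibly empty.
#' @param frame_interval_s sampling interval (s).
#' @return list with `period_s`, `omega_rad_s`, `omitted`, `reason`.
#' @export
block_frequency <- function(periods, frame_interval_s) {
  if (length(periods) == 0)
    return(list(period_s = NA_real_, omega_rad_s = NA_real_,
                omitted = TRUE, reason = "no peaks"))
  bins <- round(periods / frame_interval_s)
  tab <- table(bins)
  best <- as.integer(names(tab)[tab == max(tab)])
  T_mode <- max(best) * frame_interval_s   # tie -> longer period
  omega <- 2 * pi / T_mode
  if (omega > omega_noise_cutoff(frame_interval_s))
    return(list(period_s = T_mode, omega_rad_s = omega, omitted = TRUE,
                reason = "above half-Nyquist cutoff"))
  list(period_s = T_mode, omega_rad_s = omega, omitted = FALSE, reason = "")
}

#' Map thickness-oscillation frequency over the start-block grid
#'
#' Runs [smooth_series()], [peak_periods()] and [block_frequency()] on every
#' block of a [grid_mean_series()].
#'
#' @param grid a `grid_time_series`.
#' @param f,iter,prominence_frac smoothing and peak-detection parameters.
#' @return an `oscillation_map`: tibble with `block_row`, `block_col`,
#'   `period_s`, `omega_rad_s`, `omitted`, `reason`; attribute
#'   `frame_interval_s`.
#' @export
oscillation_map <- function(grid, f = 0.1, iter = 2, prominence_frac = 0.1) {
  stopifnot(inherits(grid, "grid_time_series"))
  dt <- grid$frame_interval_s
  res <- lapply(seq_len(nrow(grid$series)), function(i) {
    sm <- smooth_series(grid$series[i, ], f = f, iter = iter)
    block_frequency(peak_periods(sm, dt, prominence_frac), dt)
  })
  out <- tibble::tibble(
    block_row = grid$block_row, block_col = grid$block_col,
    period_s = vapply(res, `[[`, numeric(1), "period_s"),
    omega_rad_s = vapply(res, `[[`, numeric(1), "omega_rad_s"),
    omitted = vapply(res, `[[`, logical(1), "omitted"),
    reason = vapply(res, `[[`, character(1), "reason"))
  attr(out, "frame_interval_s") <- dt
  class(out) <- c("oscillation_map", class(out))
  out
}

#' Representative sample frequency: median over retained blocks
#'
#' @param map an `oscillation_map`.
#' @return median angular frequency (rad/s) over blocks not omitted.
#' @export
sample_frequency <- function(map) {
  stopifnot(inherits(map, "oscillation_map"))
  kept <- map$omega_rad_s[!map$omitted]
  if (length(kept) == 0) stop("all blocks were omitted")
  stats::median(kept)
}

#' Normalize frequencies by the same-day control median
#'
#' @param values angular frequencies to normalize.
#' @param control_values same-day control frequencies.
#' @return normalized frequencies (control median maps to 1).
#' @export
normalize_frequency <- function(values, control_values) {
  normalize_by_control(values, control_values, statistic = "median")
}
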