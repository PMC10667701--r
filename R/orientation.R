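#' Power-weighted distribution of spectral direction angles
#'
#' Container for the output of 2-D Fourier analysis of a tube-network image:
#' direction angles of the retained spectral bins, folded to \[0, 180) because
#' the power spectrum is point symmetric, each weighted by its spectral power.
#'
#' @param angles_deg numeric vector of angles, folded mod 180.
#' @param weights nonnegative powers, same length.
#' @param empty flag set when the source image carried no non-DC power.
#' @return an `angle_distribution` object.
#' @export
angle_distribution <- function(angles_deg = numeric(0),
                               weights = numeric(0), empty = length(angles_deg) == 0) {
  if (length(angles_deg) != length(weights))
    stop("angles and weights must have equal length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(list(angles_deg = fold180(angles_deg), weights = weights,
                 empty = empty), class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  if (x$empty) cat("<angle_distribution: empty>\n")
  else cat(sprintf("<angle_distribution: %d bins, total power %.3g>\n",
                   length(x$angles_deg), sum(x$weights)))
  invisible(x)
}

#' Tube-orientation angle distribution by 2-D FFT
#'
#' The square crop is mean-centred, Hann-windowed (suppresses the axis bias
#' that edge leakage of a nonperiodic scene would otherwise introduce) and
#' Fourier transformed.  Each spectral bin inside the radial frequency band
#' contributes its direction angle `atan2` of the frequency vector, folded to
#' \[0, 180), weighted by spectral power.  The DC bin and bins outside the
#' band are excluded.  Note the spectral angle is orthogonal to the physical
#' tube direction; see [tube_angle_from_spectral()].
#'
#' @param image square [gray_image()] or matrix, side >= 64 px.
#' @param band radial band `c(f_lo, f_hi)` in cycles/px; default keeps
#'   wavelengths between 4 px and a quarter of the image side.
#' @param window `"hann"` or `"none"`.
#' @return an [angle_distribution()]; empty (flagged) for a constant image.
#' @export
power_spectrum_angles <- function(image, band = NULL,
                                  window = c("hann", "none")) {
  window <- match.arg(window)
  m <- as_pixels(image)
  n <- nrow(m)
  if (n != ncol(m)) stop("image must be square for FFT analysis")
  if (n < 64) stop("image side must be at least 64 px")
  if (is.null(band)) band <- c(4 / n, 1 / 4)
  z <- m - mean(m)
  if (max(abs(z)) < 1e-9) return(angle_distribution(empty = TRUE))
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    z <- z * outer(w, w)
  }
  P <- Mod(stats::fft(z))^2
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fr <- matrix(f, n, n)                 # frequency along rows
  fc <- matrix(f, n, n, byrow = TRUE)   # frequency along columns
  rho <- sqrt(fr^2 + fc^2)
  keep <- rho >= band[1] & rho <= band[2] & rho > 0
  if (!any(keep)) return(angle_distribution(empty = TRUE))
  # y points up while rows run down, hence -fr
  ang <- fold180(atan2(-fr[keep], fc[keep]) * 180 / pi)
  angle_distribution(ang, P[keep])
}

# Silverman's rule on the weighted sample, with the angle treated circularly
# on its 180-degree support (doubled-angle representation avoids wrap bias)
silverman_bw_circular <- function(angles_deg, weights) {
  sw <- sum(weights)
  z <- complex(argument = 2 * angles_deg * pi / 180)
  rbar <- min(Mod(sum(weights * z)) / sw, 1)
  sigma <- sqrt(-2 * log(max(rbar, 1e-12))) * (180 / pi) / 2
  neff <- sw^2 / sum(weights^2)
  max(1, min(15, 0.9 * sigma * neff^(-1 / 5)))
}

#' Characteristic angle(s): modes of the weighted angle density
#'
#' A weighted Gaussian kernel density is estimated over \[0, 180) with the
#' data replicated at +/-180 degrees to emulate the periodic support;
#' bandwidth follows Silverman's rule on the weighted sample unless given.
#' All local maxima whose density reaches `prominence_frac` of the global
#' maximum are returned, global mode first; ties break toward the smaller
#' angle.
#'
#' @param dist an [angle_distribution()] (nonempty).
#' @param bw kernel bandwidth in degrees, or `NULL` for Silverman's rule.
#' @param prominence_frac acceptance fraction of the global density maximum
#'   (default 0.25).
#' @param grid_n evaluation grid size over \[0, 180) (default 720).
#' @return list with `peak_angles_deg`, `peak_densities`, `bw`, and the full
#'   `density` grid (data frame with `angle_deg`, `density`).
#' @export
characteristic_angle <- function(dist, bw = NULL, prominence_frac = 0.25,
                                 grid_n = 720) {
  stopifnot(inherits(dist, "angle_distribution"))
  if (dist$empty || length(dist$angles_deg) == 0)
    stop("cannot estimate a characteristic angle from an empty distribution")
  a <- dist$angles_deg; w <- dist$weights
  if (sum(w) <= 0) stop("all weights are zero")
  if (is.null(bw)) bw <- silverman_bw_circular(a, w)
  step <- 180 / grid_n
  d <- stats::density(c(a - 180, a, a + 180),
                      weights = rep(w, 3) / (3 * sum(w)),
                      bw = bw, from = 0, to = 180 - step, n = grid_n)
  y <- d$y
  # periodic local maxima: compare to circular neighbours
  left <- c(y[grid_n], y[-grid_n]); right <- c(y[-1], y[1])
  is_peak <- y >= left & y > right | (y > left & y >= right)
  is_peak <- is_peak & y >= prominence_frac * max(y)
  idx <- which(is_peak)
  # collapse plateau runs to their left edge
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 1)]
  ord <- order(-y[idx], d$x[idx])
  idx <- idx[ord]
  list(peak_angles_deg = d$x[idx], peak_densities = y[idx], bw = bw,
       density = data.frame(angle_deg = d$x, density = y))
}

#' Convert a spectral direction angle to the physical tube orientation
#'
#' The power spectrum of an oriented ridge concentrates along the direction
#' orthogonal to the ridge, so the physical tube angle is the spectral angle
#' rotated a quarter turn: `(angle + 90) mod 180`.
#'
#' @param angle_deg spectral angle(s) in \[0, 180).
#' @return tube orientation angle(s) in \[0, 180).
#' @export
tube_angle_from_spectral <- function(angle_deg) fold180(angle_deg + 90)

#' Time course of major tube-orientation angles over network time
#'
#' Runs [power_spectrum_angles()], [characteristic_angle()] and
#' [tube_angle_from_spectral()] on every frame of a goal-block stack and
#' reports tube angles relative to the advancing direction of the plasmodium
#' (the orthogonality correction is applied exactly once, here, at reporting
#' time).
#'
#' @param goal_stack an [image_stack()] of square goal-block crops.
#' @param network_times numeric vector of network times t_n (minutes, <= 0),
#'   one per frame.
#' @param advance_angle_deg absolute angle of the advancing direction in the
#'   image frame (default 90, advancing up the image).
#' @param ... passed to [characteristic_angle()].
#' @return a `characteristic_angle_series`: tibble with `t_n`,
#'   `peak_angles_deg` (list), `peak_densities` (list); peaks sorted by
#'   density, global mode first.
#' @export
orientation_time_course <- function(goal_stack, network_times,
                                    advance_angle_deg = 90, ...) {
  stopifnot(inherits(goal_stack, "image_stack"))
  nf <- n_frames(goal_stack)
  if (nf == 0) stop("empty stack")
  if (length(network_times) != nf)
    stop("`network_times` must give one time per frame")
  peaks <- vector("list", nf); dens <- vector("list", nf)
  for (i in seq_len(nf)) {
    dist <- power_spectrum_angles(goal_stack$frames[[i]])
    if (dist$empty) { peaks[[i]] <- numeric(0); dens[[i]] <- numeric(0); next }
    ca <- characteristic_angle(dist, ...)
    tube <- tube_angle_from_spectral(ca$peak_angles_deg)
    peaks[[i]] <- fold180(tube - advance_angle_deg)
    dens[[i]] <- ca$peak_densities
  }
  out <- tibble::tibble(t_n = network_times, peak_angles_deg = peaks,
                        peak_densities = dens)
  class(out) <- c("characteristic_angle_series", class(out))
  out
}

#' Final-state angle distribution and day-characteristic peak angles
#'
#' Pools the per-frame peak angles (weighted by their densities) over the
#' final-state window of network time, re-estimates the weighted density and
#' returns the day's characteristic peak angle(s).
#'
#' @param series a `characteristic_angle_series` from
#'   [orientation_time_course()].
#' @param window network-time window, default `c(-300, 0)` minutes.
#' @param ... passed to [characteristic_angle()].
#' @return list with `distribution` (the pooled [angle_distribution()]),
#'   `peak_angles_deg` and `peak_densities`.
#' @export
final_state_angles <- function(series, window = c(-300, 0), ...) {
  stopifnot(inherits(series, "characteristic_angle_series"))
  sel <- series$t_n >= window[1] & series$t_n <= window[2]
  if (!any(sel)) stop("no series entries inside the final-state window")
  a <- unlist(series$peak_angles_deg[sel])
  w <- unlist(series$peak_densities[sel])
  if (length(a) == 0) stop("no peaks recorded inside the final-state window")
  pooled <- angle_distribution(a, w)
  ca <- characteristic_angle(pooled, ...)
  list(distribution = pooled, peak_angles_deg = ca$peak_angles_deg,
       peak_densities = ca$peak_densities)
}
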