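#' Resolve a threshold policy on a difference image
#'
#' `"otsu"` computes Otsu's threshold on the absolute-difference image
#' (via EBImage); a numeric value is used as a fixed threshold in intensity
#' units.  The choice of a global automatic threshold versus a fixed one is
#' configuration, since transmitted-light setups differ in contrast.
#'
#' @param diff nonnegative difference image (matrix).
#' @param policy `"otsu"` or a numeric scalar.
#' @return threshold in intensity units.
#' @keywords internal
resolve_threshold <- function(diff, policy = "otsu") {
  if (is.numeric(policy)) return(policy)
  if (!identical(policy, "otsu")) stop("unknown threshold policy")
  rng <- max(diff)
  if (rng == 0) return(Inf)  # no signal at all: nothing is foreground
  EBImage::otsu(EBImage::Image(diff / 255), range = c(0, 1)) * 255
}

#' Footprint area on the bridge at crossing completion
#'
#' The background frame (stage time t0) is subtracted from the frame at te;
#' pixels whose absolute difference exceeds the threshold are foreground, and
#' the area is their count inside the bridge ROI times the pixel area.
#'
#' @param frame_at_te,frame_at_t0 [gray_image()]s of identical shape and
#'   calibration.
#' @param roi a [bridge_roi()].
#' @param threshold_policy `"otsu"` (default) or a fixed numeric threshold.
#' @return area in mm^2.
#' @export
estimate_bridge_area <- function(frame_at_te, frame_at_t0, roi,
                                 threshold_policy = "otsu") {
  if (!identical(dim(frame_at_te), dim(frame_at_t0)))
    stop("frames must have the same shape")
  ps <- pixel_size(frame_at_te)
  roi_check(roi, frame_at_te)
  d <- abs(as_pixels(frame_at_te) - as_pixels(frame_at_t0))
  thr <- resolve_threshold(d, threshold_policy)
  sum(roi_slice(d, roi) > thr) * ps^2
}

#' Detect crossing start and completion times in a movie
#'
#' Foreground is the absolute difference from the first frame, thresholded
#' once on the frame with the strongest signal (a global policy, so empty
#' early frames stay empty).  Stage time t0 is the first frame whose largest
#' connected foreground component inside the ROI exceeds `min_pixels`
#' (a guard against noise-triggered starts); te is the elapsed time from that
#' frame to the first frame whose foreground touches the far-edge line of the
#' ROI.  t0 is reported as 0 by convention, with its frame index retained.
#'
#' @param stack an [image_stack()] covering the crossing (minutes).
#' @param roi a [bridge_roi()]; its `far_edge` is the side touching the goal.
#' @param threshold_policy `"otsu"` or fixed numeric.
#' @param min_pixels connected-pixel guard for declaring t0 (default 20).
#' @return a `stage_times` object: list with `crossed`, `t0_min` (0),
#'   `te_min`, `t0_frame`, `te_frame`.  If the front never reaches the far
#'   edge, `crossed` is `FALSE` and the time fields are `NA` (the "not
#'   crossed" signal).
#' @export
detect_crossing_times <- function(stack, roi, threshold_policy = "otsu",
                                  min_pixels = 20) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$interval_unit != "min")
    stop("crossing detection expects a stack timed in minutes")
  bg <- stack$frames[[1]]
  roi_check(roi, bg)
  diffs <- lapply(stack$frames, function(f) abs(f - bg))
  peak <- which.max(vapply(diffs, max, numeric(1)))
  thr <- resolve_threshold(diffs[[peak]], threshold_policy)
  far <- roi_far_line(roi)

  t0_frame <- NA_integer_; te_frame <- NA_integer_; guard_frame <- NA_integer_
  for (i in seq_along(diffs)) {
    fg <- roi_slice(diffs[[i]], roi) > thr
    if (is.na(t0_frame) && any(fg)) {
      lab <- EBImage::bwlabel(fg * 1)
      # the front sits at the entry edge (zero visible foreground) when
      # crossing begins, so stage time 0 is the frame before foreground
      # first clears the connected-pixel guard
      if (max(tabulate(lab[lab > 0])) >= min_pixels) {
        guard_frame <- i
        t0_frame <- max(i - 1L, 1L)
      }
    }
    if (!is.na(t0_frame)) {
      edge <- if (far$axis == "row") fg[far$index, ] else fg[, far$index]
      if (any(edge)) {
        if (i == guard_frame)
          stop("front already at the far edge when it first becomes visible; ",
               "crossing time is degenerate (te = t0)")
        te_frame <- i
        break
      }
    }
  }
  if (is.na(t0_frame) || is.na(te_frame))
    return(structure(list(crossed = FALSE, t0_min = NA_real_,
                          te_min = NA_real_, t0_frame = t0_frame,
                          te_frame = te_frame), class = "stage_times"))
  structure(list(crossed = TRUE, t0_min = 0,
                 te_min = (te_frame - t0_frame) * stack$frame_interval,
                 t0_frame = t0_frame, te_frame = te_frame),
            class = "stage_times")
}

#' @export
print.stage_times <- function(x, ...) {
  if (x$crossed)
    cat(sprintf("<stage_times: t0 = 0 (frame %d), te = %g min (frame %d)>\n",
                x$t0_frame, x$te_min, x$te_frame))
  else cat("<stage_times: not crossed>\n")
  invisible(x)
}

#' Crossing speed from bridge length and stage times
#'
#' speed = bridge length (mm) / (te - t0) (min).
#'
#' @param bridge_length_mm bridge length (default 18).
#' @param times a `stage_times` object or a numeric te in minutes.
#' @return speed in mm/min.
#' @export
crossing_speed <- function(bridge_length_mm = 18, times) {
  if (inherits(times, "stage_times")) {
    if (!times$crossed) stop("sample did not cross the bridge")
    te <- times$te_min - times$t0_min
  } else te <- times
  if (!is.finite(te) || te <= 0) stop("te must exceed t0")
  bridge_length_mm / te
}

#' Normalize values by a same-day control statistic
#'
#' Speeds are normalized by the mean of the same-day control samples;
#' oscillation frequencies by the control median.  Applied to the control
#' group itself, the chosen statistic of the result is exactly 1.
#'
#' @param values numeric vector to normalize.
#' @param control_values nonempty numeric vector of same-day control values.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return `values` divided by the control statistic.
#' @export
normalize_by_control <- function(values, control_values,
                                 statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(control_values) == 0) stop("control group is empty")
  s <- if (statistic == "mean") mean(control_values) else
    stats::median(control_values)
  if (!is.finite(s) || s == 0) stop("control statistic is zero or undefined")
  values / s
}
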