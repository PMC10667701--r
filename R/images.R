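#' Calibrated 8-bit grayscale image
#'
#' A `gray_image` is a numeric matrix of intensities in \[0, 255\] carrying its
#' spatial calibration (mm per pixel).  Rows run down the image, columns run
#' right; angles elsewhere in the package are measured counter-clockwise from
#' the +x (column) axis with y pointing up, i.e. the usual mathematical
#' convention applied after flipping the row axis.
#'
#' @param pixels numeric matrix with values in \[0, 255\].
#' @param pixel_size_mm positive scalar, physical size of one pixel edge.
#' @return a `gray_image` object.
#' @export
gray_image <- function(pixels, pixel_size_mm) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1 ||
      pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a positive scalar")
  structure(pixels, pixel_size_mm = pixel_size_mm,
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, %.4f mm/px, range [%.1f, %.1f]>\n",
              nrow(x), ncol(x), attr(x, "pixel_size_mm"), min(x), max(x)))
  invisible(x)
}

#' @rdname gray_image
#' @param x object to test or coerce.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_mm")
  if (is.null(ps)) stop("image carries no pixel size")
  ps
}

as_pixels <- function(x) {
  m <- unclass(x)
  attr(m, "pixel_size_mm") <- NULL
  m
}

#' Ordered stack of frames with a fixed acquisition interval
#'
#' @param frames list of numeric matrices (or `gray_image`s), all the same
#'   shape.
#' @param frame_interval positive scalar, time between consecutive frames.
#' @param interval_unit `"min"` or `"s"`.
#' @param pixel_size_mm positive scalar shared by all frames.
#' @param start_time acquisition time of the first frame, in `interval_unit`
#'   units (default 0).
#' @return an `image_stack` object.
#' @export
image_stack <- function(frames, frame_interval, interval_unit = c("min", "s"),
                        pixel_size_mm, start_time = 0) {
  interval_unit <- match.arg(interval_unit)
  if (!is.list(frames) || length(frames) == 0)
    stop("`frames` must be a nonempty list of matrices")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be positive")
  frames <- lapply(frames, as_pixels)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share the same shape")
  structure(list(frames = frames, frame_interval = frame_interval,
                 interval_unit = interval_unit, pixel_size_mm = pixel_size_mm,
                 start_time = start_time),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack %d frames of %d x %d px, every %g %s, %.4f mm/px>\n",
              length(x$frames), d[1], d[2], x$frame_interval,
              x$interval_unit, x$pixel_size_mm))
  invisible(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname image_stack
#' @param i frame index (1-based).
#' @export
get_frame <- function(x, i) {
  if (i < 1 || i > n_frames(x)) stop("frame index out of range")
  gray_image(x$frames[[i]], x$pixel_size_mm)
}

#' @rdname image_stack
#' @export
frame_times <- function(x) x$start_time + (seq_len(n_frames(x)) - 1) * x$frame_interval

#' Rectangular region of interest on the bridge
#'
#' Coordinates are 0-based and half-open, so `bridge_roi(0, 0, nr, nc)` covers a
#' whole `nr x nc` image.  The far edge names the side of the rectangle that
#' touches the goal block (conventionally the upper edge, `"top"`); the entry edge
#' is the opposite side.
#'
#' @param r0,c0 top-left corner (inclusive, 0-based).
#' @param r1,c1 bottom-right corner (exclusive).
#' @param far_edge which side touches the goal: `"top"`, `"bottom"`, `"left"`,
#'   `"right"`.
#' @return a `bridge_roi` object.
#' @export
bridge_roi <- function(r0, c0, r1, c1, far_edge = c("top", "bottom", "left", "right")) {
  far_edge <- match.arg(far_edge)
  if (r1 <= r0 || c1 <= c0) stop("ROI must have positive extent")
  if (r0 < 0 || c0 < 0) stop("ROI coordinates must be nonnegative")
  structure(list(r0 = as.integer(r0), c0 = as.integer(c0),
                 r1 = as.integer(r1), c1 = as.integer(c1),
                 far_edge = far_edge),
            class = "bridge_roi")
}

roi_check <- function(roi, img) {
  if (roi$r1 > nrow(img) || roi$c1 > ncol(img))
    stop("ROI lies outside the image")
  invisible(roi)
}

roi_slice <- function(img, roi) {
  as_pixels(img)[(roi$r0 + 1):roi$r1, (roi$c0 + 1):roi$c1, drop = FALSE]
}

# index of the far-edge line within the ROI slice (row or column)
roi_far_line <- function(roi) {
  switch(roi$far_edge,
         top = list(axis = "row", index = 1L),
         bottom = list(axis = "row", index = roi$r1 - roi$r0),
         left = list(axis = "col", index = 1L),
         right = list(axis = "col", index = roi$c1 - roi$c0))
}

#' Central square crop of an image
#'
#' @param img a `gray_image` or matrix.
#' @param side side length in px; default the largest even square that fits.
#' @return a matrix (calibration preserved when input is a `gray_image`).
#' @export
crop_square <- function(img, side = NULL) {
  m <- as_pixels(img)
  if (is.null(side)) side <- min(dim(m))
  side <- side - side %% 2
  if (side < 2 || side > min(dim(m))) stop("invalid crop side")
  r0 <- (nrow(m) - side) %/% 2
  c0 <- (ncol(m) - side) %/% 2
  out <- m[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)]
  if (is_gray_image(img)) gray_image(out, pixel_size(img)) else out
}

#' Fold an angle into the half-turn range \[0, 180)
#'
#' Tube orientations are axial (a tube at 10 deg is the same tube at 190 deg),
#' so all angles in the package live on \[0, 180).
#'
#' @param angle_deg numeric vector of angles in degrees.
#' @return angles reduced modulo 180.
#' @export
fold180 <- function(angle_deg) angle_deg %% 180

#' Acute deviation between two axial angles
#'
#' @param a,b angles in degrees (axial, i.e. modulo 180).
#' @return deviation in \[0, 90\].
#' @export
angle_deviation <- function(a, b = 0) {
  d <- abs(fold180(a) - fold180(b)) %% 180
  pmin(d, 180 - d)
}

#' Rotate an image counter-clockwise and crop to the valid centre
#'
#' Rotation uses bilinear interpolation; the result is cropped to the central
#' square guaranteed to contain only source pixels (side / sqrt(2) for oblique
#' angles), so spectral analysis never sees fill values.
#'
#' @param img `gray_image` or matrix (square).
#' @param phi_deg rotation angle in degrees, counter-clockwise in the
#'   y-up frame.
#' @return rotated-and-cropped image of the same class.
#' @export
rotate_crop <- function(img, phi_deg) {
  m <- as_pixels(img)
  n <- min(dim(m))
  phi <- phi_deg %% 360
  rot <- EBImage::rotate(m, phi, output.dim = dim(m), bg.col = mean(m))
  out <- as.matrix(rot)
  side <- if (phi %% 90 == 0) n else floor(n / sqrt(2))
  side <- side - side %% 2
  r0 <- (nrow(out) - side) %/% 2
  c0 <- (ncol(out) - side) %/% 2
  out <- out[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)]
  out <- pmin(pmax(out, 0), 255)
  if (is_gray_image(img)) gray_image(out, pixel_size(img)) else out
}
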