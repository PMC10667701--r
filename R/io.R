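#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 8-bit; the sidecar records the frame interval,
#' unit, pixel size and any ground-truth metadata supplied.
#'
#' @param stack an [image_stack()].
#' @param path output `.tif` path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param ground_truth optional list serialized into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, ground_truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(f) round(f) / 255),
                  path, bits.per.sample = 8)
  meta <- list(frame_interval = stack$frame_interval,
               interval_unit = stack$interval_unit,
               pixel_size_mm = stack$pixel_size_mm,
               n_frames = n_frames(stack),
               ground_truth = ground_truth)
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path `.tif` path; frame interval and calibration are taken from the
#'   JSON sidecar (or the arguments when no sidecar exists).
#' @param frame_interval,interval_unit,pixel_size_mm used when there is no
#'   sidecar.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, frame_interval = NULL,
                             interval_unit = "min", pixel_size_mm = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f * 255
  })
  side <- sub("\\.tiff?$", ".json", path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    frame_interval <- meta$frame_interval
    interval_unit <- meta$interval_unit
    pixel_size_mm <- meta$pixel_size_mm
  }
  if (is.null(frame_interval) || is.null(pixel_size_mm))
    stop("no sidecar found; supply frame_interval and pixel_size_mm")
  image_stack(frames, frame_interval, interval_unit, pixel_size_mm)
}
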