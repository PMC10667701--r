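#' Specification of a synthetic tube-network image
#'
#' Describes a field of dark, Gaussian-profile line segments (transport tubes)
#' on a bright agar background.  Tube directions are drawn from a mixture of
#' axial orientation modes; a one-mode mixture emulates a tree network (all
#' tubes near one direction), a multi-mode mixture a mesh.
#'
#' @param orientation_modes data frame (or coercible) with columns `angle_deg`
#'   (axial, reduced mod 180) and `weight` (> 0), one row per mode.
#' @param n_tubes number of tube segments to render (>= 0).
#' @param tube_width_px full width at half maximum of the tube profile, px.
#' @param tube_darkness peak intensity drop of one tube, in \[0, 255\].
#' @param image_size_px integer vector `c(rows, cols)`.
#' @param background_level agar background intensity in \[0, 255\].
#' @param noise_sd additive Gaussian pixel noise, intensity units.
#' @param angle_jitter_sd s.d. of Gaussian jitter added to each drawn angle
#'   (degrees); 0 keeps drawn angles exactly on the modes.
#' @param seed integer RNG seed.
#' @return a `tube_network_spec` object.
#' @export
tube_network_spec <- function(orientation_modes, n_tubes = 40,
                              tube_width_px = 3, tube_darkness = 120,
                              image_size_px = c(192, 192),
                              background_level = 200, noise_sd = 2,
                              angle_jitter_sd = 0, seed = 1) {
  om <- as.data.frame(orientation_modes)
  if (nrow(om) == 0 || !all(c("angle_deg", "weight") %in% names(om)))
    stop("`orientation_modes` needs columns angle_deg and weight, one row per mode")
  if (any(om$weight <= 0)) stop("mode weights must be positive")
  om$angle_deg <- fold180(om$angle_deg)
  if (tube_width_px <= 0) stop("`tube_width_px` must be positive")
  if (n_tubes < 0) stop("`n_tubes` must be nonnegative")
  if (tube_darkness < 0 || tube_darkness > 255)
    stop("`tube_darkness` must lie in [0, 255]")
  structure(list(orientation_modes = om, n_tubes = as.integer(n_tubes),
                 tube_width_px = tube_width_px, tube_darkness = tube_darkness,
                 image_size_px = as.integer(image_size_px),
                 background_level = background_level, noise_sd = noise_sd,
                 angle_jitter_sd = angle_jitter_sd, seed = as.integer(seed)),
            class = "tube_network_spec")
}

# Gaussian-profile segment rendering: each tube subtracts
# darkness * exp(-d^2 / 2 sigma^2) where d is distance to the segment and
# sigma = fwhm / 2.355, giving the spectrum a band-limited ridge.
render_tubes <- function(canvas, angles_deg, darkness, width_px, rel_length = 0.4) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  sigma <- width_px / 2.355
  cc <- col(canvas); rr <- row(canvas)
  x <- cc; y <- nr + 1 - rr
  for (a in angles_deg) {
    th <- a * pi / 180
    x0 <- stats::runif(1, 0.15, 0.85) * nc
    y0 <- stats::runif(1, 0.15, 0.85) * nr
    L <- rel_length * min(nr, nc)
    dx <- cos(th); dy <- sin(th)
    px <- x - x0; py <- y - y0
    t <- pmin(pmax(px * dx + py * dy, -L), L)
    d2 <- (px - t * dx)^2 + (py - t * dy)^2
    canvas <- canvas - darkness * exp(-d2 / (2 * sigma^2))
  }
  canvas
}

#' Render a synthetic tube-network image with known orientations
#'
#' @param spec a [tube_network_spec()].
#' @return list with `image` (a [gray_image()]) and `drawn_angles_deg`, the
#'   exact axial angle of every rendered tube.
#' @export
make_tube_network_image <- function(spec) {
  stopifnot(inherits(spec, "tube_network_spec"))
  set.seed(spec$seed)
  om <- spec$orientation_modes
  canvas <- matrix(spec$background_level,
                   spec$image_size_px[1], spec$image_size_px[2])
  if (spec$n_tubes > 0) {
    idx <- sample.int(nrow(om), spec$n_tubes, replace = TRUE,
                      prob = om$weight)
    drawn <- om$angle_deg[idx]
    if (spec$angle_jitter_sd > 0)
      drawn <- fold180(drawn + stats::rnorm(length(drawn), 0, spec$angle_jitter_sd))
    canvas <- render_tubes(canvas, drawn, spec$tube_darkness, spec$tube_width_px)
  } else {
    drawn <- numeric(0)
  }
  if (spec$noise_sd > 0)
    canvas <- canvas + stats::rnorm(length(canvas), 0, spec$noise_sd)
  canvas <- pmin(pmax(canvas, 0), 255)
  list(image = gray_image(canvas, pixel_size_mm = 0.0625),
       drawn_angles_deg = drawn)
}

#' Convenience: render a tree-like or mesh-like goal network
#'
#' A tree network has a single orientation mode nearly parallel to the
#' advancing direction; a mesh adds a second, near-perpendicular mode.  Angles
#' are given relative to the advancing direction (0 deg = parallel).
#'
#' @param state `"tree"` or `"mesh"`.
#' @param advance_angle_deg absolute angle of the advancing direction in the
#'   image frame (default 90, i.e. advancing up the image).
#' @param parallel_angle_deg relative angle of the parallel mode (default 20).
#' @param oblique_angle_deg relative angle of the mesh's second mode
#'   (default 75).
#' @param seed RNG seed.
#' @param ... further arguments passed to [tube_network_spec()].
#' @return as [make_tube_network_image()].
#' @export
make_network_state_image <- function(state = c("tree", "mesh"),
                                     advance_angle_deg = 90,
                                     parallel_angle_deg = 20,
                                     oblique_angle_deg = 75,
                                     seed = 1, ...) {
  state <- match.arg(state)
  modes <- if (state == "tree") {
    data.frame(angle_deg = fold180(advance_angle_deg + parallel_angle_deg),
               weight = 1)
  } else {
    data.frame(angle_deg = fold180(advance_angle_deg +
                                     c(parallel_angle_deg, oblique_angle_deg)),
               weight = c(1, 1))
  }
  make_tube_network_image(tube_network_spec(modes, seed = seed, ...))
}

#' Specification of a synthetic bridge-crossing movie
#'
#' A binary plasmodium footprint advances at constant speed from the entry
#' edge (bottom) toward the far edge (top) of an 18 x 18 mm bridge, then is
#' blurred and darkened onto the agar background frame by frame.
#'
#' @param speed_mm_per_min front speed (> 0).  The implied crossing time
#'   `bridge_length_mm / speed` must be an integer number of frames.
#' @param bridge_length_mm,bridge_width_mm bridge dimensions (default 18 x 18).
#' @param footprint `"string"` (thin path), `"branched"` (trunk plus side
#'   branches), or `"sheet"` (full-width coverage).
#' @param frame_interval_min acquisition interval (default 5).
#' @param pixel_size_mm calibration (default 0.0625, mid-range of typical
#'   transmitted-light setups).
#' @param string_width_px width of string/branch strands in px.
#' @param darkness,background_level,noise_sd rendering parameters as in
#'   [tube_network_spec()].
#' @param blur_sd_px Gaussian blur applied to the footprint before darkening
#'   (0 disables; then rendered foreground equals the binary mask exactly).
#' @param lead_frames background-only frames prepended before motion starts.
#' @param seed RNG seed.
#' @return a `crossing_movie_spec` object.
#' @export
crossing_movie_spec <- function(speed_mm_per_min, bridge_length_mm = 18,
                                bridge_width_mm = 18,
                                footprint = c("string", "branched", "sheet"),
                                frame_interval_min = 5, pixel_size_mm = 0.0625,
                                string_width_px = 3, darkness = 120,
                                background_level = 200, noise_sd = 1,
                                blur_sd_px = 0.7, lead_frames = 2, seed = 1) {
  footprint <- match.arg(footprint)
  if (speed_mm_per_min <= 0) stop("`speed_mm_per_min` must be positive")
  te <- bridge_length_mm / speed_mm_per_min
  if (abs(te / frame_interval_min - round(te / frame_interval_min)) > 1e-8)
    stop("crossing time bridge_length/speed must be an integer number of frames")
  structure(list(speed_mm_per_min = speed_mm_per_min,
                 bridge_length_mm = bridge_length_mm,
                 bridge_width_mm = bridge_width_mm, footprint = footprint,
                 frame_interval_min = frame_interval_min,
                 pixel_size_mm = pixel_size_mm,
                 string_width_px = string_width_px, darkness = darkness,
                 background_level = background_level, noise_sd = noise_sd,
                 blur_sd_px = blur_sd_px, lead_frames = as.integer(lead_frames),
                 seed = as.integer(seed)),
            class = "crossing_movie_spec")
}

# full-extent binary footprint masks; the advancing front later reveals the
# part within d px of the entry (bottom) edge
footprint_mask <- function(spec, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  w <- max(1L, round(spec$string_width_px))
  half <- (w - 1) %/% 2
  if (spec$footprint == "sheet") {
    m[] <- TRUE
  } else {
    c_main <- round(nc * stats::runif(1, 0.35, 0.65))
    wig <- round(3 * sin(seq_len(nr) / nr * 2 * pi))
    for (r in seq_len(nr)) {
      cm <- min(max(c_main + wig[r], half + 1), nc - half)
      m[r, (cm - half):(cm + w - 1 - half)] <- TRUE
    }
    if (spec$footprint == "branched") {
      for (b in 1:3) {
        r_start <- round(nr * stats::runif(1, 0.3, 0.8))
        dirn <- sample(c(-1, 1), 1)
        len <- round(nr * 0.25)
        for (k in seq_len(len)) {
          r <- r_start - k
          if (r < 1) break
          cm <- c_main + dirn * round(k * 0.7)
          if (cm < half + 1 || cm > nc - half) break
          m[r, (cm - half):(cm + w - 1 - half)] <- TRUE
        }
      }
    }
  }
  m
}

#' Generate a bridge-crossing movie with known crossing time and area
#'
#' @param spec a [crossing_movie_spec()].
#' @return list with `stack` (an [image_stack()], minutes), `t0_min` (0 by
#'   convention), `t0_frame` (1-based index of the first frame at stage time
#'   0), `te_min` (= bridge_length / speed), `final_area_mm2` (area of the
#'   binary footprint when crossing completes) and `final_mask`.
#' @export
make_crossing_movie <- function(spec) {
  stopifnot(inherits(spec, "crossing_movie_spec"))
  set.seed(spec$seed)
  nr <- round(spec$bridge_length_mm / spec$pixel_size_mm)
  nc <- round(spec$bridge_width_mm / spec$pixel_size_mm)
  te <- spec$bridge_length_mm / spec$speed_mm_per_min
  n_move <- round(te / spec$frame_interval_min)
  fp <- footprint_mask(spec, nr, nc)
  mm_per_frame <- spec$speed_mm_per_min * spec$frame_interval_min
  px_per_frame <- mm_per_frame / spec$pixel_size_mm

  frames <- vector("list", spec$lead_frames + n_move + 1)
  masks <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    k <- i - spec$lead_frames - 1   # frames advanced since stage time 0
    d_px <- max(0, k) * px_per_frame
    mask <- fp & (row(fp) > nr - d_px)
    img <- matrix(spec$background_level, nr, nc)
    if (any(mask)) {
      layer <- mask * 1
      if (spec$blur_sd_px > 0)
        layer <- as.matrix(EBImage::gblur(layer, sigma = spec$blur_sd_px))
      img <- img - spec$darkness * layer
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    frames[[i]] <- pmin(pmax(img, 0), 255)
    masks[[i]] <- mask
  }
  final_mask <- masks[[length(masks)]]
  list(stack = image_stack(frames, spec$frame_interval_min, "min",
                           spec$pixel_size_mm),
       t0_min = 0, t0_frame = spec$lead_frames + 1, te_min = te,
       final_area_mm2 = sum(final_mask) * spec$pixel_size_mm^2,
       final_mask = final_mask)
}

#' Specification of a synthetic thickness-oscillation movie
#'
#' Per-block sinusoidal intensity modulation on a uniform baseline, sampled at
#' 5-s intervals for 10 min by default (121 frames, inclusive of t = 0).
#'
#' @param period_field matrix of oscillation periods T (seconds), one entry
#'   per block of the block grid, or a scalar for a uniform field.
#' @param amplitude modulation amplitude, intensity units.
#' @param frame_interval_s sampling interval (default 5).
#' @param duration_s recording length (default 600); must be divisible by
#'   `frame_interval_s`.
#' @param noise_sd per-pixel Gaussian noise.
#' @param baseline background intensity level.
#' @param block_px block edge in pixels (default 10).
#' @param grid_blocks blocks per side (default 32, i.e. a 320 x 320 px ROI).
#' @param pixel_size_mm calibration.
#' @param seed RNG seed.
#' @return an `oscillation_movie_spec` object.
#' @export
oscillation_movie_spec <- function(period_field = 100, amplitude = 30,
                                   frame_interval_s = 5, duration_s = 600,
                                   noise_sd = 2, baseline = 150,
                                   block_px = 10, grid_blocks = 32,
                                   pixel_size_mm = 0.0625, seed = 1) {
  if (duration_s %% frame_interval_s != 0)
    stop("`duration_s` must be divisible by `frame_interval_s`")
  if (length(period_field) == 1)
    period_field <- matrix(period_field, grid_blocks, grid_blocks)
  if (!is.matrix(period_field) ||
      !all(dim(period_field) == c(grid_blocks, grid_blocks)))
    stop("`period_field` must be a grid_blocks x grid_blocks matrix or scalar")
  if (any(period_field <= 0)) stop("periods must be positive")
  if (baseline + amplitude > 255 || baseline - amplitude < 0)
    stop("baseline +/- amplitude must stay within [0, 255]")
  structure(list(period_field = period_field, amplitude = amplitude,
                 frame_interval_s = frame_interval_s, duration_s = duration_s,
                 noise_sd = noise_sd, baseline = baseline,
                 block_px = as.integer(block_px),
                 grid_blocks = as.integer(grid_blocks),
                 pixel_size_mm = pixel_size_mm, seed = as.integer(seed)),
            class = "oscillation_movie_spec")
}

#' Generate a thickness-oscillation movie with a known period map
#'
#' @param spec an [oscillation_movie_spec()].
#' @return list with `stack` (121 frames at the defaults, seconds),
#'   `period_field` (the programmed T per block) and `omega_field`
#'   (2 pi / T, rad/s).
#' @export
make_oscillation_movie <- function(spec) {
  stopifnot(inherits(spec, "oscillation_movie_spec"))
  set.seed(spec$seed)
  nfr <- spec$duration_s / spec$frame_interval_s + 1
  side <- spec$grid_blocks * spec$block_px
  ones <- matrix(1, spec$block_px, spec$block_px)
  frames <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    t <- (i - 1) * spec$frame_interval_s
    blockvals <- spec$baseline +
      spec$amplitude * sin(2 * pi * t / spec$period_field)
    img <- kronecker(blockvals, ones)
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    frames[[i]] <- pmin(pmax(img, 0), 255)
  }
  list(stack = image_stack(frames, spec$frame_interval_s, "s",
                           spec$pixel_size_mm),
       period_field = spec$period_field,
       omega_field = 2 * pi / spec$period_field)
}

#' Render well-separated tubes spanning the bridge
#'
#' Fixture for connection typing: `n_tubes` near-vertical dark tubes run the
#' full height of the image at well-separated columns, connecting the
#' entry-side boundary to the goal-side boundary.
#'
#' @param n_tubes number of spanning tubes (0 gives a blank bridge).
#' @param image_size_px `c(rows, cols)`.
#' @param tube_width_px,tube_darkness,background_level,noise_sd as in
#'   [tube_network_spec()].
#' @param tilt_sd_deg s.d. of the random tilt of each tube from vertical.
#' @param seed RNG seed.
#' @return list with `image` (a [gray_image()]) and `tube_columns`, the column
#'   of each tube at mid-height.
#' @export
make_spanning_tube_image <- function(n_tubes, image_size_px = c(240, 240),
                                     tube_width_px = 3, tube_darkness = 120,
                                     background_level = 200, noise_sd = 2,
                                     tilt_sd_deg = 3, seed = 1) {
  if (n_tubes < 0) stop("`n_tubes` must be nonnegative")
  set.seed(seed)
  nr <- image_size_px[1]; nc <- image_size_px[2]
  canvas <- matrix(background_level, nr, nc)
  sigma <- tube_width_px / 2.355
  cols <- numeric(0)
  if (n_tubes > 0) {
    # evenly spaced lanes with jitter keeps tubes well separated
    lane <- nc / (n_tubes + 1)
    cols <- lane * seq_len(n_tubes) +
      stats::runif(n_tubes, -0.2 * lane, 0.2 * lane)
    rr <- row(canvas); cc <- col(canvas)
    for (x0 in cols) {
      tilt <- stats::rnorm(1, 0, tilt_sd_deg) * pi / 180
      # column of the tube centreline as a function of row
      ctr <- x0 + tan(tilt) * (rr - nr / 2)
      d2 <- (cc - ctr)^2
      canvas <- canvas - tube_darkness * exp(-d2 / (2 * sigma^2))
    }
  }
  if (noise_sd > 0)
    canvas <- canvas + stats::rnorm(length(canvas), 0, noise_sd)
  canvas <- pmin(pmax(canvas, 0), 255)
  list(image = gray_image(canvas, pixel_size_mm = 0.0625),
       tube_columns = cols)
}

#' Specification of a synthetic study table
#'
#' Draws per-sample behavioural indices for a day x condition design with
#' configurable additive day effects, for exercising the statistical workflow.
#'
#' @param n_per_cell replicates per (condition, day) cell (>= 3 for cells that
#'   enter multiple comparisons).
#' @param conditions character vector of condition labels.
#' @param days integer vector of day labels.
#' @param baseline named list of baseline values per index, e.g.
#'   `list(area = 30, speed = 0.15, omega = 0.06)`.
#' @param day_effects nested list `day_effects[[condition]][[index]]`, a
#'   vector of additive shifts (one per day); missing entries mean no effect.
#' @param dispersion named list of between-sample dispersions per index
#'   (s.d. for the normal family, sdlog for the lognormal family).
#' @param family `"normal"` or `"lognormal"`.
#' @param seed RNG seed.
#' @return a `study_table_spec` object.
#' @export
study_table_spec <- function(n_per_cell = 16,
                             conditions = c("control", "quinine"),
                             days = 1:4,
                             baseline = list(area = 30, speed = 0.15,
                                             omega = 0.06),
                             day_effects = list(),
                             dispersion = list(area = 5, speed = 0.03,
                                               omega = 0.008),
                             family = c("normal", "lognormal"), seed = 1) {
  family <- match.arg(family)
  if (n_per_cell < 1) stop("`n_per_cell` must be at least 1")
  if (any(unlist(dispersion) < 0)) stop("dispersions must be nonnegative")
  structure(list(n_per_cell = as.integer(n_per_cell), conditions = conditions,
                 days = as.integer(days), baseline = baseline,
                 day_effects = day_effects, dispersion = dispersion,
                 family = family, seed = as.integer(seed)),
            class = "study_table_spec")
}

#' Generate a study table with known cell means
#'
#' @param spec a [study_table_spec()].
#' @return a tibble with one row per (condition, day, replicate) and one
#'   column per index, plus `sample_id`; attribute `cell_means` holds the
#'   configured noise-free mean of every cell.
#' @export
make_study_table <- function(spec) {
  stopifnot(inherits(spec, "study_table_spec"))
  set.seed(spec$seed)
  idx_names <- names(spec$baseline)
  rows <- expand.grid(replicate = seq_len(spec$n_per_cell),
                      day = spec$days, condition = spec$conditions,
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(
    sample_id = sprintf("%s_r%02d", substr(rows$condition, 1, 3),
                        rows$replicate),
    condition = rows$condition, day = rows$day)
  means <- out[c("condition", "day")]
  for (ix in idx_names) {
    mu <- rep(spec$baseline[[ix]], nrow(rows))
    for (cond in names(spec$day_effects)) {
      eff <- spec$day_effects[[cond]][[ix]]
      if (is.null(eff)) next
      sel <- rows$condition == cond
      mu[sel] <- mu[sel] + eff[match(rows$day[sel], spec$days)]
    }
    disp <- spec$dispersion[[ix]]
    if (is.null(disp)) disp <- 0
    val <- if (spec$family == "normal") {
      mu + stats::rnorm(length(mu), 0, disp)
    } else {
      mu * exp(stats::rnorm(length(mu), 0, disp))
    }
    out[[ix]] <- val
    means[[ix]] <- mu
  }
  attr(out, "cell_means") <- means
  attr(out, "seed") <- spec$seed
  out
}

#' Stack of goal-network images for one day's final-state window
#'
#' Renders `n_frames` independent network images of the given state spread
#' evenly over the final-state window of network time.
#'
#' @param state `"tree"` or `"mesh"`.
#' @param n_frames frames in the window (>= 2).
#' @param window network-time window in minutes (default `c(-300, 0)`).
#' @param seed RNG seed.
#' @param ... passed to [make_network_state_image()].
#' @return list with `stack` (an [image_stack()], minutes) and
#'   `network_times`.
#' @export
make_goal_day_stack <- function(state, n_frames = 3, window = c(-300, 0),
                                seed = 1, ...) {
  if (n_frames < 2) stop("need at least two frames")
  imgs <- lapply(seq_len(n_frames), function(i) {
    make_network_state_image(state, seed = seed * 1009L + i, ...)$image
  })
  t_n <- seq(window[1], window[2], length.out = n_frames)
  list(stack = image_stack(imgs, frame_interval = diff(window) / (n_frames - 1),
                           interval_unit = "min", pixel_size_mm = 0.0625),
       network_times = t_n)
}
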