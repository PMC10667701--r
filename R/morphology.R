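#' Classify a day's network as tree or mesh from its peak angles
#'
#' A network is a tree when every characteristic peak angle is nearly parallel
#' to the direction the plasmodium tip was advancing (acute deviation
#' < 45 degrees); any peak at 45 degrees or more marks the network as
#' multidirectional, i.e. mesh.
#'
#' @param peak_angles_deg nonempty numeric vector of tube-frame peak angles
#'   in \[0, 180), folded so the advancing direction is 0.
#' @param parallel_limit_deg the parallel criterion (default 45).
#' @return a `network_state`: list with `label` (`"tree"` or `"mesh"`) and
#'   `evidence` (the acute deviations of the peaks, for audit).
#' @export
classify_network_state <- function(peak_angles_deg, parallel_limit_deg = 45) {
  if (length(peak_angles_deg) == 0) stop("peak angle list is empty")
  dev <- angle_deviation(peak_angles_deg, 0)
  label <- if (all(dev < parallel_limit_deg)) "tree" else "mesh"
  structure(list(label = label,
                 evidence = data.frame(peak_angle_deg = fold180(peak_angles_deg),
                                       deviation_deg = dev)),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state: %s (peaks at %s deg from advance)>\n", x$label,
              paste(round(x$evidence$deviation_deg, 1), collapse = ", ")))
  invisible(x)
}

state_label <- function(s) {
  if (inherits(s, "network_state")) s$label
  else match.arg(tolower(as.character(s)), c("tree", "mesh"))
}

#' Classify a 4-day tree/mesh trajectory into daily-change Types 0-5
#'
#' Type 0: tree on all four days; Types 1-3: the network turns
#' multidirectional on Day 4, 3 or 2 respectively (and stays so); Type 4:
#' mesh on all days; Type 5: any other sequence.  The five monotone
#' tree-to-mesh sequences map to Types 0-4 and the remaining 11 sequences to
#' Type 5.
#'
#' @param states length-4 list/vector of `network_state`s or `"tree"`/`"mesh"`
#'   labels, Days 1-4 in order.
#' @return integer type id in 0..5.
#' @export
classify_daily_type <- function(states) {
  if (length(states) != 4) stop("exactly four daily states are required")
  lab <- vapply(states, state_label, character(1))
  key <- paste(ifelse(lab == "tree", "T", "M"), collapse = "")
  switch(key,
         TTTT = 0L, TTTM = 1L, TTMM = 2L, TMMM = 3L, MMMM = 4L,
         5L)
}

#' Per-condition frequencies of daily-change types
#'
#' @param table data frame with columns `condition` and `daily_type` (one row
#'   per sample), or additionally `sample_id`, `day`, `network_state` from
#'   which 4-day types are first assembled per sample.
#' @return tibble with `condition`, `daily_type`, `n`, `ratio`; ratios sum to
#'   1 within each condition.
#' @export
type_distribution <- function(table) {
  if (nrow(table) == 0) stop("empty study table")
  if (!"daily_type" %in% names(table)) {
    if (!all(c("sample_id", "day", "network_state") %in% names(table)))
      stop("need either `daily_type` or (`sample_id`, `day`, `network_state`)")
    sp <- split(table, list(table$condition, table$sample_id), drop = TRUE)
    table <- do.call(rbind, lapply(sp, function(d) {
      d <- d[order(d$day), ]
      data.frame(condition = d$condition[1], sample_id = d$sample_id[1],
                 daily_type = classify_daily_type(d$network_state))
    }))
  }
  counts <- as.data.frame(table(condition = table$condition,
                                daily_type = table$daily_type),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  tot <- tapply(counts$Freq, counts$condition, sum)
  tibble::tibble(condition = counts$condition,
                 daily_type = as.integer(counts$daily_type),
                 n = counts$Freq,
                 ratio = counts$Freq / as.numeric(tot[counts$condition]))
}

#' Classify one day's network state directly from goal-block images
#'
#' Full image path: orientation time course, final-state pooling, then the
#' tree/mesh rule on the day-characteristic peak angles.
#'
#' @param stack [image_stack()] of square goal crops.
#' @param network_times network time per frame (minutes, <= 0).
#' @param advance_angle_deg absolute advancing direction (default 90).
#' @param window final-state window (default `c(-300, 0)`).
#' @param ... passed to [characteristic_angle()] via the pipeline.
#' @return a `network_state`.
#' @export
classify_day_from_images <- function(stack, network_times,
                                     advance_angle_deg = 90,
                                     window = c(-300, 0), ...) {
  ser <- orientation_time_course(stack, network_times, advance_angle_deg, ...)
  fin <- final_state_angles(ser, window)
  classify_network_state(fin$peak_angles_deg)
}
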