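#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels of a binary mask until only a 1-px-wide
#' skeleton remains, using the classic two-subiteration Zhang-Suen rules
#' (implemented vectorised over the whole mask).
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(m) {
    z <- matrix(FALSE, nr + 2, nc + 2)
    z[2:(nr + 1), 2:(nc + 1)] <- m
    z
  }
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      P2 <- p[i - 1, j]; P3 <- p[i - 1, j + 1]; P4 <- p[i, j + 1]
      P5 <- p[i + 1, j + 1]; P6 <- p[i + 1, j]; P7 <- p[i + 1, j - 1]
      P8 <- p[i, j - 1]; P9 <- p[i - 1, j - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- if (step == 1) {
        m & B >= 2 & B <= 6 & A == 1 & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        m & B >= 2 & B <= 6 & A == 1 & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# cluster sorted positions: runs whose gaps exceed `gap` start a new cluster
count_clusters <- function(pos, gap) {
  if (length(pos) == 0) return(0L)
  pos <- sort(pos)
  sum(c(TRUE, diff(pos) > gap))
}

#' Count and type the tube connections spanning the bridge
#'
#' Tubes (dark on a bright background, or bright on dark: only the absolute
#' deviation from the background level matters) are binarized, skeletonized
#' within the bridge ROI, and skeleton components that span from the
#' entry-side boundary to the goal-side boundary are identified.  The tube
#' count is the number of distinct crossings of the bridge midline by
#' spanning components, with crossings closer than `merge_distance_px`
#' merged (skeleton spurs at junctions would otherwise inflate the count).
#' A plasmodium merely present on the bridge without a spanning path counts
#' as no connection.
#'
#' Counts map to the connection type labels: 0 tubes = `n` (no connection),
#' 1 = `s` (single), 2 = `d` (double), and 3 or more = `t` (triple; larger
#' counts are included in this category).
#'
#' @param final_image [gray_image()] of the final network.
#' @param roi a [bridge_roi()]; spanning is judged between its entry and far
#'   edges.
#' @param threshold_policy `"otsu"` (on the absolute deviation from the
#'   median background) or a fixed numeric threshold.
#' @param merge_distance_px crossings closer than this are counted once
#'   (default 9, about three tube widths).
#' @param edge_pad_px rows replicated beyond each boundary before thinning so
#'   skeleton ends stay anchored at the boundaries (default 8).
#' @param min_contrast minimum separation (intensity units) between the mean
#'   foreground and mean background deviation for the binarization to count
#'   as real tube signal; below it the bridge is treated as blank.  Guards
#'   against automatic thresholds splitting pure noise (default 20).
#' @return a `connection_type`: list with `label` in `{n, s, d, t}` and
#'   `tube_count`.
#' @export
count_bridge_connections <- function(final_image, roi,
                                     threshold_policy = "otsu",
                                     merge_distance_px = 9,
                                     edge_pad_px = 8, min_contrast = 20) {
  roi_check(roi, final_image)
  sl <- roi_slice(final_image, roi)
  # orient so the spanning direction runs along rows (entry at bottom)
  if (roi$far_edge %in% c("left", "right")) sl <- t(sl)
  if (roi$far_edge %in% c("bottom", "right")) sl <- sl[nrow(sl):1, ]
  dev <- abs(sl - stats::median(sl))
  thr <- resolve_threshold(dev, threshold_policy)
  fg <- dev > thr
  if (!any(fg) || all(fg)) return(connection_type(0L))
  if (mean(dev[fg]) - mean(dev[!fg]) < min_contrast)
    return(connection_type(0L))
  # anchor tube ends: replicate the boundary rows before thinning
  top <- fg[rep(1L, edge_pad_px), , drop = FALSE]
  bot <- fg[rep(nrow(fg), edge_pad_px), , drop = FALSE]
  sk <- skeletonize(rbind(top, fg, bot))
  sk <- sk[(edge_pad_px + 1):(edge_pad_px + nrow(fg)), , drop = FALSE]
  # label with 8-connectivity: a 1-px skeleton steps diagonally, which plain
  # 4-connected labelling would fragment, so label a 3x3 dilation and read
  # the labels back at the skeleton pixels
  dil <- EBImage::dilate(sk * 1, EBImage::makeBrush(3, shape = "box"))
  lab <- as.matrix(EBImage::bwlabel(dil)) * sk
  top_ids <- unique(lab[1, ][lab[1, ] > 0])
  bot_ids <- unique(lab[nrow(lab), ][lab[nrow(lab), ] > 0])
  span <- intersect(top_ids, bot_ids)
  if (length(span) == 0) return(connection_type(0L))
  keep <- matrix(lab %in% span, nrow(lab), ncol(lab))
  # count distinct crossings of the midline (3-row band for robustness)
  mid <- nrow(keep) %/% 2
  band <- keep[max(1, mid - 1):min(nrow(keep), mid + 1), , drop = FALSE]
  cols <- which(colSums(band) > 0)
  connection_type(count_clusters(cols, merge_distance_px))
}

#' Connection type from a tube count
#'
#' @param tube_count nonnegative integer.
#' @return a `connection_type` object.
#' @export
connection_type <- function(tube_count) {
  if (tube_count < 0) stop("tube count must be nonnegative")
  label <- if (tube_count == 0) "n" else if (tube_count == 1) "s"
  else if (tube_count == 2) "d" else "t"
  structure(list(label = label, tube_count = as.integer(tube_count)),
            class = "connection_type")
}

#' @export
print.connection_type <- function(x, ...) {
  cat(sprintf("<connection_type: %s (%d tube%s)>\n", x$label, x$tube_count,
              if (x$tube_count == 1) "" else "s"))
  invisible(x)
}

#' Cross-tabulate connection types with network morphology
#'
#' @param table data frame with columns `condition`, `network_state`
#'   (`"tree"`/`"mesh"`) and `connection_type` (`n`/`s`/`d`/`t`).
#' @return tibble with `condition`, `network_state`, `connection_type`, `n`,
#'   `ratio`; ratios sum to 1 within each (condition, network_state) cell and
#'   empty cells are simply absent.
#' @export
connection_by_morphology <- function(table) {
  need <- c("condition", "network_state", "connection_type")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "))
  if (nrow(table) == 0) stop("empty table")
  counts <- as.data.frame(table(condition = table$condition,
                                network_state = table$network_state,
                                connection_type = table$connection_type),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  key <- paste(counts$condition, counts$network_state)
  tot <- tapply(counts$Freq, key, sum)
  tibble::tibble(condition = counts$condition,
                 network_state = counts$network_state,
                 connection_type = counts$connection_type,
                 n = counts$Freq,
                 ratio = counts$Freq / as.numeric(tot[key]))
}
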