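## Frame-differencing ("dynamic pixel change") locomotion backend.

#' Count changed pixels between two frames within an ROI
#'
#' The dynamic pixel-change measure: the number of ROI pixels whose absolute
#' intensity difference between the two frames exceeds `threshold`.
#'
#' @param frame_a,frame_b Intensity matrices of identical dimensions.
#' @param threshold Intensity difference threshold (>= 0); a pixel counts
#'   only if `|b - a| > threshold`.
#' @param roi Optional ROI as a list/row with `x_min`, `y_min`, `x_max`,
#'   `y_max` (0-based half-open pixel rectangle); default whole frame.
#' @return Integer count in `[0, roi area]`.
#' @export
frame_change_count <- function(frame_a, frame_b, threshold = 20, roi = NULL) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop2("frame dimensions differ: ",
          paste(dim(frame_a), collapse = "x"), " vs ",
          paste(dim(frame_b), collapse = "x"))
  assert_scalar_num(threshold, "threshold", nonneg = TRUE)
  if (!is.null(roi)) {
    frame_a <- roi_sub(frame_a, roi)
    frame_b <- roi_sub(frame_b, roi)
  }
  sum(abs(frame_a - frame_b) > threshold)
}

## 3x3 median filter, replicate padding. Exact via the median-of-medians
## decomposition for 9 elements (sort each column-triple, then take the
## median of {max of minima, median of medians, min of maxima}).
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

#' 3x3 median filter
#'
#' Fully vectorised 3x3 median smoothing with replicate edge padding. Removes
#' single-pixel impulse noise and one-pixel-wide line artefacts (the
#' "dark-line" stripes some camera/LED combinations produce) while leaving
#' larger blobs essentially intact.
#'
#' @param m Intensity matrix.
#' @return Filtered matrix, same dimensions and storage mode.
#' @export
median_filter3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 2L || w < 2L) return(m)
  up <- m[c(1L, 1L:(h - 1L)), , drop = FALSE]
  dn <- m[c(2L:h, h), , drop = FALSE]
  colmed <- function(x) {                       # vertical sort of each triple
    lo <- pmin(up, x, dn); hi <- pmax(up, x, dn)
    list(lo = lo, mid = up + x + dn - lo - hi, hi = hi)
  }
  s <- colmed(m)
  shift_l <- function(x) x[, c(1L, 1L:(w - 1L)), drop = FALSE]
  shift_r <- function(x) x[, c(2L:w, w), drop = FALSE]
  a <- pmax(shift_l(s$lo), s$lo, shift_r(s$lo))
  b <- med3(shift_l(s$mid), s$mid, shift_r(s$mid))
  cc <- pmin(shift_l(s$hi), s$hi, shift_r(s$hi))
  out <- med3(a, b, cc)
  storage.mode(out) <- storage.mode(m)
  out
}

#' Per-tank pixel-activity series for a video
#'
#' Runs frame differencing over every adjacent frame pair and sums changed
#' pixels per tank ROI, producing one activity series per tank (length
#' `n_frames - 1`).
#'
#' @param seq A [frame_sequence] with >= 2 frames.
#' @param layout A [tank_layout] whose ROIs fit inside the frame.
#' @param threshold Intensity change threshold (default 20 on the 8-bit
#'   scale).
#' @param denoise If `TRUE`, each frame is 3x3 median-filtered before
#'   differencing (off by default; use for recordings with line artefacts).
#' @return List of `activity_series` objects, one per tank, each a list with
#'   `tank_id`, `counts`, `threshold_used`, `fps`.
#' @export
activity_series <- function(seq, layout, threshold = 20, denoise = FALSE) {
  if (!inherits(seq, "frame_sequence")) stop2("seq must be a frame_sequence")
  if (!inherits(layout, "tank_layout")) stop2("layout must be a tank_layout")
  n <- length(seq$frames)
  if (n < 2L) stop2("need at least 2 frames to difference")
  check_layout_in_frame(layout, seq$width, seq$height)
  tanks <- layout$tanks
  nt <- nrow(tanks)
  counts <- matrix(0L, nrow = n - 1L, ncol = nt)
  prev <- seq$frames[[1L]]
  if (denoise) prev <- median_filter3(prev)
  for (i in 2L:n) {
    cur <- seq$frames[[i]]
    if (denoise) cur <- median_filter3(cur)
    changed <- abs(cur - prev) > threshold
    for (k in seq_len(nt))
      counts[i - 1L, k] <- sum(roi_sub(changed, tanks[k, ]))
    prev <- cur
  }
  lapply(seq_len(nt), function(k)
    structure(list(tank_id = tanks$tank_id[k], counts = counts[, k],
                   threshold_used = threshold, fps = seq$fps),
              class = "activity_series"))
}

#' Reduce an activity series to one interval-level scalar
#'
#' The mean changed-pixel count per frame pair — one number per recording
#' interval (e.g. per 1-min hourly recording), so that interval length does
#' not rescale the metric.
#'
#' @param series An `activity_series` (or bare numeric count vector).
#' @return Mean changed pixels per frame pair.
#' @export
interval_activity <- function(series) {
  counts <- if (inherits(series, "activity_series")) series$counts else series
  if (length(counts) == 0L) stop2("empty activity series")
  mean(counts)
}

#' Turn a list of activity series into a tidy data.frame
#'
#' One row per tank per frame pair: `tank_id, frame_index, changed_pixels`
#' (frame_index is the 0-based index of the first frame of the pair). This is
#' the CSV schema of the `pixelact` command-line tool.
#'
#' @param series_list List of `activity_series`.
#' @return data.frame.
#' @export
activity_to_df <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s)
    data.frame(tank_id = s$tank_id,
               frame_index = seq_along(s$counts) - 1L,
               changed_pixels = s$counts)))
}
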