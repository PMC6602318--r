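## Background-subtraction centroid tracker with proximity linking.
##
## This stands in for appearance-based multi-animal trackers as a coordinate
## source only: within-tank identities are maintained by nearest-proximity
## assignment, not by visual fingerprints, which is sufficient for tank-level
## circadian aggregates (documented limitation).

#' Estimate a static background as the per-pixel temporal median
#'
#' @param seq A [frame_sequence].
#' @param n_samples Number of frames, evenly spaced in time, entering the
#'   median (default: up to 25).
#' @return Numeric background matrix.
#' @export
estimate_background <- function(seq, n_samples = min(25L, length(seq$frames))) {
  n <- length(seq$frames)
  if (n_samples < 1L || n_samples > n)
    stop2("n_samples must be in [1, ", n, "]")
  idx <- unique(round(seq(1L, n, length.out = n_samples)))
  stack <- matrix(unlist(seq$frames[idx]), ncol = length(idx))
  bg <- apply(stack, 1L, median.default)
  matrix(bg, nrow = seq$height)
}

## 8-connected component labelling of a logical mask, union-find over the
## foreground pixel list (masks are small: a few blobs per tank).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  nfg <- length(fg)
  if (nfg == 0L) return(list(labels = integer(0), pixels = fg))
  id_of <- integer(h * w)
  id_of[fg] <- seq_len(nfg)
  parent <- seq_len(nfg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  for (k in seq_len(nfg)) {
    r <- rows[k]; cc <- cols[k]; p <- fg[k]
    ## union with already-visited neighbours: left, and the three above-row
    ## pixels of the left/current/right columns
    nb <- c(if (r > 1L) p - 1L,                       # up
            if (cc > 1L) p - h,                        # left
            if (cc > 1L && r > 1L) p - h - 1L,         # up-left
            if (cc < w && r > 1L) p + h - 1L)          # up-right
    for (q in nb) {
      j <- id_of[q]
      if (j > 0L) {
        rj <- find(j); rk <- find(k)
        if (rj != rk) parent[rk] <- rj
      }
    }
  }
  labels <- vapply(seq_len(nfg), find, integer(1))
  list(labels = match(labels, unique(labels)), pixels = fg)
}

#' Segment one frame into per-tank detections
#'
#' Foreground is `|frame - background| > seg_threshold`; 8-connected
#' components inside each tank ROI with pixel area in `[min_area, max_area]`
#' become detections, localised by their intensity-weighted centroid
#' (weights = absolute background difference). If a tank yields more
#' components than its expected fish count, the largest ones are kept.
#'
#' @param frame,background Matrices of identical dimensions.
#' @param layout A [tank_layout].
#' @param seg_threshold Intensity threshold (default 30).
#' @param min_area Minimum blob area in pixels (default 10).
#' @param max_area Maximum blob area; default 10% of the ROI area.
#' @param frame_index Index stored in the output rows (0-based convention is
#'   the caller's choice).
#' @return data.frame with columns `frame_index, tank_id, x, y, area`
#'   (x, y in pixels, sub-pixel).
#' @export
segment_frame <- function(frame, background, layout, seg_threshold = 30,
                          min_area = 10L, max_area = NULL,
                          frame_index = 0L) {
  if (!identical(dim(frame), dim(background)))
    stop2("frame and background dimensions differ")
  diffm <- abs(frame - background)
  out <- vector("list", nrow(layout$tanks))
  for (k in seq_len(nrow(layout$tanks))) {
    roi <- layout$tanks[k, ]
    sub <- roi_sub(diffm, roi)
    lab <- label_components(sub > seg_threshold)
    if (length(lab$pixels) == 0L) { out[[k]] <- NULL; next }
    amax <- max_area %||% (0.1 * roi_area(roi))
    if (min_area > amax) stop2("min_area exceeds max_area")
    h <- nrow(sub)
    areas <- tabulate(lab$labels)
    keep <- which(areas >= min_area & areas <= amax)
    if (length(keep) == 0L) { out[[k]] <- NULL; next }
    if (length(keep) > roi$expected_fish)
      keep <- keep[order(areas[keep], decreasing = TRUE)][
        seq_len(roi$expected_fish)]
    rowsub <- ((lab$pixels - 1L) %% h)          # 0-based y within ROI
    colsub <- ((lab$pixels - 1L) %/% h)         # 0-based x within ROI
    wts <- sub[lab$pixels]
    det <- lapply(keep, function(lb) {
      sel <- lab$labels == lb
      wsum <- sum(wts[sel])
      data.frame(frame_index = frame_index, tank_id = roi$tank_id,
                 x = roi$x_min + sum(colsub[sel] * wts[sel]) / wsum,
                 y = roi$y_min + sum(rowsub[sel] * wts[sel]) / wsum,
                 area = areas[lb])
    })
    out[[k]] <- do.call(rbind, det)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame_index = integer(0), tank_id = integer(0),
                      x = numeric(0), y = numeric(0), area = integer(0))
  res
}

## minimum-total-distance assignment of tracks to detections.
## cost: n_tracks x n_det matrix, Inf = forbidden. Exhaustive over
## permutations when both sides <= 4 (the chamber holds <= 3-4 fish per
## tank); greedy nearest-pair otherwise. Returns detection index per track
## (NA = unmatched).
assign_detections <- function(cost) {
  nt <- nrow(cost); nd <- ncol(cost)
  if (nt == 0L || nd == 0L) return(rep(NA_integer_, nt))
  if (nt <= 4L && nd <= 4L) {
    m <- max(nt, nd)
    big <- 1e8
    sq <- matrix(big, m, m)
    sq[seq_len(nt), seq_len(nd)] <- ifelse(is.finite(cost), cost, big)
    perms <- permutations_of(m)
    tot <- apply(perms, 1L, function(p) sum(sq[cbind(seq_len(m), p)]))
    best <- perms[which.min(tot), ]
    out <- best[seq_len(nt)]
    out[sq[cbind(seq_len(nt), out)] >= big] <- NA_integer_
    out
  } else {
    out <- rep(NA_integer_, nt)
    used <- logical(nd)
    repeat {
      cost[is.na(cost)] <- Inf
      i <- which.min(cost)
      if (length(i) == 0L || !is.finite(cost[i])) break
      r <- ((i - 1L) %% nt) + 1L
      cc <- ((i - 1L) %/% nt) + 1L
      out[r] <- cc
      cost[r, ] <- Inf
      cost[, cc] <- Inf
      if (all(!is.na(out)) || all(!is.finite(cost))) break
    }
    out
  }
}

## all permutations of 1..n as an (n!) x n matrix (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Link per-frame detections into fixed-identity trajectories
#'
#' Within each tank, detections are assigned to tracks by minimum-total-
#' distance matching; an assignment is rejected when the jump exceeds
#' `max_jump * (gap + 1)` centimetres, where `gap` is the number of frames
#' the track has coasted. Gaps up to `max_gap` frames are later filled by
#' linear interpolation (counted per trajectory in `n_interpolated`); longer
#' gaps hold the last seen position. Exactly `expected_fish` full-length
#' trajectories are returned per tank; a tank with no detections at all
#' yields all-missing trajectories with a warning.
#'
#' @param detections data.frame as produced by [segment_frame()] over all
#'   frames (`frame_index` must cover `0:(n_frames-1)` of the video).
#' @param layout A [tank_layout].
#' @param n_frames Total frame count of the source video.
#' @param fps Frame rate.
#' @param max_jump Maximum plausible per-frame displacement, cm.
#' @param max_gap Maximum gap length (frames) filled by interpolation.
#' @return List of `trajectory` objects: lists with `fish_id`, `tank_id`,
#'   `positions` (n_frames x 2 matrix, cm, tank-local origin at the tank's
#'   top-left corner), `fps`, `n_interpolated`, `observed` (logical).
#' @export
link_tracks <- function(detections, layout, n_frames, fps,
                        max_jump = 5, max_gap = 5L) {
  stopifnot(n_frames >= 1L)
  ppc <- layout$px_per_cm
  max_jump_px <- max_jump * ppc
  trajs <- list()
  for (k in seq_len(nrow(layout$tanks))) {
    roi <- layout$tanks[k, ]
    nf <- roi$expected_fish
    det <- detections[detections$tank_id == roi$tank_id, , drop = FALSE]
    pos <- array(NA_real_, c(n_frames, 2L, nf))
    if (nrow(det) == 0L) {
      warning("tank ", roi$tank_id,
              ": no detections in any frame; returning all-missing ",
              "trajectories", call. = FALSE)
    } else {
      last_pos <- matrix(NA_real_, nf, 2L)      # last seen, px
      last_seen <- rep(-1L, nf)                  # frame index of last obs
      det_by_frame <- split(seq_len(nrow(det)), det$frame_index)
      for (fi in 0:(n_frames - 1L)) {
        rows <- det_by_frame[[as.character(fi)]]
        if (is.null(rows)) next
        dx <- det$x[rows]; dy <- det$y[rows]
        nd <- length(rows)
        live <- which(last_seen >= 0L)
        assigned_det <- rep(FALSE, nd)
        if (length(live) > 0L) {
          cost <- matrix(Inf, length(live), nd)
          for (a in seq_along(live)) {
            tr <- live[a]
            d <- sqrt((dx - last_pos[tr, 1L])^2 + (dy - last_pos[tr, 2L])^2)
            gap <- fi - last_seen[tr] - 1L
            d[d > max_jump_px * (gap + 1L)] <- Inf
            cost[a, ] <- d
          }
          sel <- assign_detections(cost)
          for (a in seq_along(live)) {
            if (!is.na(sel[a])) {
              tr <- live[a]; j <- sel[a]
              pos[fi + 1L, , tr] <- c(dx[j], dy[j])
              last_pos[tr, ] <- c(dx[j], dy[j])
              last_seen[tr] <- fi
              assigned_det[j] <- TRUE
            }
          }
        }
        ## seed fresh tracks with leftover detections
        for (j in which(!assigned_det)) {
          free <- which(last_seen < 0L)
          if (length(free) == 0L) break
          tr <- free[1L]
          pos[fi + 1L, , tr] <- c(dx[j], dy[j])
          last_pos[tr, ] <- c(dx[j], dy[j])
          last_seen[tr] <- fi
        }
      }
    }
    for (f in seq_len(nf)) {
      p <- pos[, , f, drop = FALSE]
      dim(p) <- c(n_frames, 2L)
      filled <- fill_gaps(p, max_gap)
      ## tank-local cm coordinates
      pcm <- cbind((filled$pos[, 1L] - roi$x_min) / ppc,
                   (filled$pos[, 2L] - roi$y_min) / ppc)
      trajs[[length(trajs) + 1L]] <-
        trajectory(pcm, fps = fps, fish_id = f, tank_id = roi$tank_id,
                   n_interpolated = filled$n_interpolated,
                   observed = !is.na(p[, 1L]))
    }
  }
  trajs
}

## interpolate interior NA runs of length <= max_gap; hold-last for longer
## runs and for trailing NAs; back-fill leading NAs. All-NA input returned
## unchanged.
fill_gaps <- function(pos, max_gap) {
  n <- nrow(pos)
  obs <- which(!is.na(pos[, 1L]))
  if (length(obs) == 0L)
    return(list(pos = pos, n_interpolated = 0L))
  n_interp <- 0L
  if (obs[1L] > 1L) pos[seq_len(obs[1L] - 1L), ] <-
      rep(pos[obs[1L], ], each = obs[1L] - 1L)
  if (length(obs) > 1L) for (i in seq_len(length(obs) - 1L)) {
    a <- obs[i]; b <- obs[i + 1L]
    gap <- b - a - 1L
    if (gap == 0L) next
    idx <- (a + 1L):(b - 1L)
    if (gap <= max_gap) {
      w <- (idx - a) / (b - a)
      pos[idx, 1L] <- pos[a, 1L] + w * (pos[b, 1L] - pos[a, 1L])
      pos[idx, 2L] <- pos[a, 2L] + w * (pos[b, 2L] - pos[a, 2L])
      n_interp <- n_interp + gap
    } else {
      pos[idx, ] <- rep(pos[a, ], each = gap)
    }
  }
  last <- obs[length(obs)]
  if (last < n) pos[(last + 1L):n, ] <- rep(pos[last, ], each = n - last)
  list(pos = pos, n_interpolated = n_interp)
}

#' Trajectory constructor
#'
#' @param positions n x 2 matrix of (x, y) positions in cm (may contain NA
#'   rows for missing frames).
#' @param fps Frame rate.
#' @param fish_id,tank_id Identifiers.
#' @param n_interpolated Count of gap-filled entries.
#' @param observed Logical vector marking frames with a real detection.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(positions, fps, fish_id = 1L, tank_id = 1L,
                       n_interpolated = 0L, observed = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop2("positions must be an n x 2 matrix")
  assert_scalar_num(fps, "fps", positive = TRUE)
  structure(list(fish_id = fish_id, tank_id = tank_id,
                 positions = positions, fps = as.numeric(fps),
                 n_interpolated = as.integer(n_interpolated),
                 observed = observed %||% !is.na(positions[, 1L])),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> tank %s fish %s: %d frames @ %.6g fps, %d interpolated\n",
    x$tank_id, x$fish_id, nrow(x$positions), x$fps, x$n_interpolated))
  invisible(x)
}

#' Convert a pixel-space trajectory to centimetres
#'
#' @param traj_px A `trajectory` whose positions are in pixels.
#' @param px_per_cm Positive calibration factor.
#' @return The trajectory with positions divided by `px_per_cm`.
#' @export
calibrate <- function(traj_px, px_per_cm) {
  assert_scalar_num(px_per_cm, "px_per_cm", positive = TRUE)
  traj_px$positions <- traj_px$positions / px_per_cm
  traj_px
}

#' Track a whole video: background, segmentation, linking
#'
#' Convenience wrapper running [estimate_background()], [segment_frame()]
#' on every frame and [link_tracks()].
#'
#' @param seq A [frame_sequence].
#' @param layout A [tank_layout].
#' @param seg_threshold,min_area,max_area Segmentation parameters, see
#'   [segment_frame()].
#' @param max_jump,max_gap Linking parameters, see [link_tracks()].
#' @param n_bg_samples Frames entering the background median.
#' @return List of `trajectory` objects (cm, tank-local coordinates).
#' @export
track_video <- function(seq, layout, seg_threshold = 30, min_area = 10L,
                        max_area = NULL, max_jump = 5, max_gap = 5L,
                        n_bg_samples = min(25L, length(seq$frames))) {
  check_layout_in_frame(layout, seq$width, seq$height)
  bg <- estimate_background(seq, n_bg_samples)
  dets <- vector("list", length(seq$frames))
  for (i in seq_along(seq$frames))
    dets[[i]] <- segment_frame(seq$frames[[i]], bg, layout, seg_threshold,
                               min_area, max_area, frame_index = i - 1L)
  link_tracks(do.call(rbind, dets), layout, n_frames = length(seq$frames),
              fps = seq$fps, max_jump = max_jump, max_gap = max_gap)
}

#' Write / read trajectory tables
#'
#' Tidy CSV schema, one row per fish per frame:
#' `frame, tank_id, fish_id, x_cm, y_cm, interpolated`. `read_trajectories`
#' also accepts externally produced tables of this schema (e.g. converted
#' multi-animal tracker output).
#'
#' @param trajs List of `trajectory` objects.
#' @param path CSV path.
#' @param fps Frame rate to attach on read.
#' @return `write_trajectories`: `path` invisibly. `read_trajectories`: list
#'   of `trajectory` objects.
#' @export
write_trajectories <- function(trajs, path) {
  df <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(frame = seq_len(nrow(tr$positions)) - 1L,
               tank_id = tr$tank_id, fish_id = tr$fish_id,
               x_cm = tr$positions[, 1L], y_cm = tr$positions[, 2L],
               interpolated = as.integer(!tr$observed))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, fps) {
  df <- utils::read.csv(path)
  need <- c("frame", "tank_id", "fish_id", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop2("trajectory CSV must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (tk in unique(df$tank_id)) for (fi in unique(df$fish_id[
    df$tank_id == tk])) {
    d <- df[df$tank_id == tk & df$fish_id == fi, ]
    d <- d[order(d$frame), ]
    obs <- if ("interpolated" %in% names(d)) d$interpolated == 0 else
      rep(TRUE, nrow(d))
    out[[length(out) + 1L]] <-
      trajectory(cbind(d$x_cm, d$y_cm), fps = fps, fish_id = fi,
                 tank_id = tk, n_interpolated = sum(!obs), observed = obs)
  }
  out
}
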