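## Per-fish locomotion endpoints over one recording interval.

#' Kinematics configuration
#'
#' Thresholds for the time-movement ratios and the sleep-bout rule. The
#' freezing and rapid speed cutoffs follow common adult-zebrafish behavioural
#' convention (they are not biological constants and should be tuned per
#' species); the 5-second minimum defines sleep-like quiescence.
#'
#' @param v_freeze Speed below which a step counts as freezing, cm/s.
#' @param v_rapid Speed above which a step counts as rapid movement, cm/s.
#' @param sleep_min_duration Minimum duration of a quiescence bout to count
#'   as sleep-like, seconds (bouts must *exceed* this, strictly).
#' @param displacement_epsilon Displacements below this (cm) are treated as
#'   zero and excluded from heading statistics.
#' @return List of class `kinematics_config`.
#' @export
kinematics_config <- function(v_freeze = 1.0, v_rapid = 10.0,
                              sleep_min_duration = 5.0,
                              displacement_epsilon = 1e-6) {
  if (v_freeze < 0 || v_rapid <= v_freeze)
    stop2("need 0 <= v_freeze < v_rapid")
  assert_scalar_num(sleep_min_duration, "sleep_min_duration", positive = TRUE)
  structure(list(v_freeze = v_freeze, v_rapid = v_rapid,
                 sleep_min_duration = sleep_min_duration,
                 displacement_epsilon = displacement_epsilon),
            class = "kinematics_config")
}

traj_positions <- function(traj) {
  p <- if (inherits(traj, "trajectory")) traj$positions else as.matrix(traj)
  if (anyNA(p))
    stop2("trajectory contains missing positions; fill gaps before ",
          "computing kinematics")
  p
}

#' Per-step swimming speeds
#'
#' `v_i = ||p_{i+1} - p_i|| * fps`, cm/s; total distance is
#' `sum(v_i) / fps`.
#'
#' @param traj A `trajectory` (positions in cm) or an n x 2 matrix.
#' @param fps Frame rate (taken from the trajectory if absent).
#' @return Numeric vector of length `n - 1`.
#' @export
step_speeds <- function(traj, fps = NULL) {
  p <- traj_positions(traj)
  fps <- fps %||% (if (inherits(traj, "trajectory")) traj$fps else
    stop2("fps required for bare position matrices"))
  if (nrow(p) < 2L) stop2("need at least 2 positions")
  d <- diff(p)
  sqrt(rowSums(d^2)) * fps
}

#' Signed turning angles along a trajectory
#'
#' Angle between successive headings `p_i -> p_{i+1}` and
#' `p_{i+1} -> p_{i+2}`, degrees in `(-180, 180]`, positive counterclockwise
#' in the plane of the coordinates. Entries are `NA` (undefined) whenever
#' either segment is shorter than `eps` — a motionless fish has no heading.
#'
#' @param traj Trajectory or n x 2 matrix (>= 3 positions).
#' @param eps Minimum segment length, cm.
#' @return Numeric vector of length `n - 2`, possibly with NAs.
#' @export
turning_angles <- function(traj, eps = 1e-6) {
  p <- traj_positions(traj)
  if (nrow(p) < 3L) stop2("need at least 3 positions")
  d <- diff(p)
  len <- sqrt(rowSums(d^2))
  n <- nrow(d)
  u <- d[-n, , drop = FALSE]; v <- d[-1L, , drop = FALSE]
  cross <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  dot <- u[, 1L] * v[, 1L] + u[, 2L] * v[, 2L]
  ang <- atan2(cross, dot) * 180 / pi
  ang[len[-n] < eps | len[-1L] < eps] <- NA_real_
  ang
}

#' Detect sleep-like quiescence bouts
#'
#' A bout is a maximal run of consecutive steps with speed `< v_freeze`
#' whose duration (run length / fps) strictly exceeds
#' `sleep_min_duration` — the "inactivity over 5 s" operational definition
#' of sleep-like behaviour in fish.
#'
#' @param speeds Per-step speed vector, cm/s.
#' @param fps Frame rate.
#' @param cfg A [kinematics_config()].
#' @return List with `bouts` (data.frame `start_step`, `end_step`, 1-based
#'   inclusive step indices, and `duration_s`) and `sleep_time_fraction`
#'   (total bout time / interval time).
#' @export
detect_sleep_bouts <- function(speeds, fps, cfg = kinematics_config()) {
  if (length(speeds) == 0L) stop2("empty speed series")
  quiet <- speeds < cfg$v_freeze
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & (r$lengths / fps > cfg$sleep_min_duration)
  bouts <- data.frame(start_step = starts[sel], end_step = ends[sel],
                      duration_s = r$lengths[sel] / fps)
  list(bouts = bouts,
       sleep_time_fraction = sum(bouts$duration_s) / (length(speeds) / fps))
}

#' Summarise a trajectory into the standard locomotion endpoints
#'
#' Computes, for one fish over one recording interval: total distance (cm),
#' average speed (cm/s), average angular velocity (deg/s, mean absolute turn
#' times fps over defined angles), meandering (total absolute turning per
#' distance, deg/cm), the freezing / swimming / rapid time-movement ratios
#' (fractions of steps with `v < v_freeze`, `v_freeze <= v <= v_rapid`,
#' `v > v_rapid`; they sum to 1), and sleep-bout statistics.
#'
#' @param traj Trajectory (cm) with >= 3 positions.
#' @param cfg A [kinematics_config()].
#' @param fps Frame rate (from the trajectory if absent).
#' @param fish_id,interval_id Identifiers copied into the output.
#' @return List of class `kinematics_summary`.
#' @export
summarize_kinematics <- function(traj, cfg = kinematics_config(), fps = NULL,
                                 fish_id = NULL, interval_id = NA) {
  fps <- fps %||% (if (inherits(traj, "trajectory")) traj$fps else
    stop2("fps required for bare position matrices"))
  p <- traj_positions(traj)
  if (nrow(p) < 3L) stop2("need at least 3 positions")
  v <- step_speeds(traj, fps)
  total_distance <- sum(v) / fps
  ang <- turning_angles(traj, cfg$displacement_epsilon)
  abs_ang <- abs(ang[!is.na(ang)])
  degenerate <- total_distance < cfg$displacement_epsilon
  meandering <- if (degenerate) 0 else sum(abs_ang) / total_distance
  sleep <- detect_sleep_bouts(v, fps, cfg)
  structure(list(
    fish_id = fish_id %||% (if (inherits(traj, "trajectory")) traj$fish_id
                            else NA),
    interval_id = interval_id,
    total_distance = total_distance,
    average_speed = mean(v),
    average_angular_velocity = if (length(abs_ang)) mean(abs_ang) * fps else 0,
    meandering = meandering,
    freezing_ratio = mean(v < cfg$v_freeze),
    swimming_ratio = mean(v >= cfg$v_freeze & v <= cfg$v_rapid),
    rapid_ratio = mean(v > cfg$v_rapid),
    sleep_bout_count = nrow(sleep$bouts),
    sleep_time_fraction = sleep$sleep_time_fraction,
    degenerate = degenerate,
    config = cfg), class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<kinematics_summary> fish %s interval %s\n",
           "  distance %.3g cm, speed %.3g cm/s, ang.vel %.3g deg/s, ",
           "meandering %.3g deg/cm\n",
           "  ratios f/s/r %.3f/%.3f/%.3f, sleep bouts %d (%.3f of time)\n"),
    x$fish_id, x$interval_id, x$total_distance, x$average_speed,
    x$average_angular_velocity, x$meandering, x$freezing_ratio,
    x$swimming_ratio, x$rapid_ratio, x$sleep_bout_count,
    x$sleep_time_fraction))
  invisible(x)
}

#' Flatten kinematics summaries to a data.frame
#'
#' One row per fish per interval, including the thresholds used — the CSV
#' schema of the `kinematics` command-line tool.
#'
#' @param summaries List of `kinematics_summary` objects.
#' @return data.frame.
#' @export
kinematics_to_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(fish_id = s$fish_id, interval_id = s$interval_id,
               total_distance = s$total_distance,
               average_speed = s$average_speed,
               average_angular_velocity = s$average_angular_velocity,
               meandering = s$meandering,
               freezing_ratio = s$freezing_ratio,
               swimming_ratio = s$swimming_ratio,
               rapid_ratio = s$rapid_ratio,
               sleep_bout_count = s$sleep_bout_count,
               sleep_time_fraction = s$sleep_time_fraction,
               v_freeze = s$config$v_freeze, v_rapid = s$config$v_rapid,
               sleep_min_duration = s$config$sleep_min_duration)))
}
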