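## End-to-end study analysis: hourly videos -> both backends -> circadian
## profiles.

## tank-mean interval speed from tracked trajectories; an all-missing
## trajectory (fish never detected, i.e. it never moved off the background)
## is scored as stationary (speed 0) rather than dropped.
mean_tracked_speed <- function(trajs) {
  sp <- vapply(trajs, function(tr) {
    if (anyNA(tr$positions)) 0
    else mean(step_speeds(tr))
  }, 0)
  mean(sp)
}

#' Analyze a recorded (or synthetic) circadian study directory
#'
#' Processes each `hour_HH.tif`/`.avi` video with both backends: pixel
#' activity (frame differencing per tank) and tracking plus kinematics
#' (tank-mean swimming speed). Returns one row per hour per tank.
#'
#' @param dir Directory holding `fixture_config.toml` and hourly videos.
#' @param threshold Pixel-change intensity threshold.
#' @param denoise Median-filter frames before differencing.
#' @param seg_threshold,max_jump,max_gap Tracker parameters.
#' @return List with `per_tank` (data.frame: hour, tank_id, activity,
#'   speed), `layout`, `schedule`, `start_clock_time`.
#' @export
analyze_study <- function(dir, threshold = 20, denoise = FALSE,
                          seg_threshold = 30, max_jump = 5, max_gap = 5L) {
  cfg <- read_config(file.path(dir, "fixture_config.toml"))
  layout <- layout_from_config(cfg)
  schedule <- schedule_from_config(cfg)
  fps <- cfg$study$fps
  videos <- sort(list.files(dir, pattern = "^hour_[0-9]+\\.(tif|tiff|avi)$",
                            full.names = TRUE))
  if (length(videos) == 0L) stop2("no hour_* videos found in ", dir)
  rows <- list()
  for (v in videos) {
    hh <- as.integer(sub("^hour_([0-9]+)\\..*$", "\\1", basename(v)))
    seq <- read_frames(v, fps = fps)
    act <- activity_series(seq, layout, threshold = threshold,
                           denoise = denoise)
    trajs <- suppressWarnings(
      track_video(seq, layout, seg_threshold = seg_threshold,
                  max_jump = max_jump, max_gap = max_gap))
    tanks <- layout$tanks$tank_id
    for (k in seq_along(tanks)) {
      tk_trajs <- Filter(function(tr) tr$tank_id == tanks[k], trajs)
      rows[[length(rows) + 1L]] <- data.frame(
        hour = hh, tank_id = tanks[k],
        activity = interval_activity(act[[k]]),
        speed = mean_tracked_speed(tk_trajs))
    }
  }
  per_tank <- do.call(rbind, rows)
  per_tank <- per_tank[order(per_tank$hour, per_tank$tank_id), ]
  list(per_tank = per_tank, layout = layout, schedule = schedule,
       start_clock_time = cfg$study$start_clock_time %||% 0)
}

#' Summarise a study analysis into whole-chamber circadian profiles
#'
#' Pools tanks per hour (mean over tanks) and assembles light/dark-labelled
#' profiles for both backends, plus their cross-method Spearman agreement
#' after min-max normalization.
#'
#' @param analysis Result of [analyze_study()].
#' @return List with `activity_profile`, `speed_profile`
#'   (`circadian_profile` objects), `classification` (per backend) and
#'   `cross_validation` (rho, p).
#' @export
summarize_study <- function(analysis) {
  pt <- analysis$per_tank
  hours <- sort(unique(pt$hour))
  act <- vapply(hours, function(h) mean(pt$activity[pt$hour == h]), 0)
  spd <- vapply(hours, function(h) mean(pt$speed[pt$hour == h]), 0)
  start <- analysis$start_clock_time
  ap <- assemble_profile(act, analysis$schedule, start,
                         metric_name = "pixel_activity", subject_id = "chamber")
  sp <- assemble_profile(spd, analysis$schedule, start,
                         metric_name = "tank_mean_speed",
                         subject_id = "chamber")
  list(activity_profile = ap, speed_profile = sp,
       classification = list(pixel_activity = phase_means(ap)$classification,
                             tracker = phase_means(sp)$classification),
       cross_validation = cross_validate_backends(act, spd))
}
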