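## Ground-truthed synthetic behaviour: a two-state (active/quiescent)
## continuous-time Markov chain discretised at frame resolution drives a
## correlated random walk inside a reflecting tank. Defaults emulate a
## diurnal zebrafish-like animal: sustained swimming in the light phase and
## long (> 5 s expected) quiescence bouts in the dark phase; the nocturnal
## (catfish-like) profile mirrors the phases.

#' Per-phase behaviour parameters
#'
#' @param dwell_active_s,dwell_quiescent_s Mean dwell times (s) of the
#'   active / quiescent states (exponential).
#' @param speed_mean_cms Mean active swimming speed, cm/s (lognormal).
#' @param speed_sdlog Lognormal sigma of the per-frame active speed.
#' @param turn_sd_deg Wrapped-normal per-frame heading change while active,
#'   degrees.
#' @return List of class `phase_behavior`.
#' @export
phase_behavior <- function(dwell_active_s, dwell_quiescent_s, speed_mean_cms,
                           speed_sdlog = 0.4, turn_sd_deg = 30) {
  stopifnot(dwell_active_s > 0, dwell_quiescent_s > 0, speed_mean_cms >= 0)
  structure(list(dwell_active_s = dwell_active_s,
                 dwell_quiescent_s = dwell_quiescent_s,
                 speed_mean_cms = speed_mean_cms,
                 speed_sdlog = speed_sdlog,
                 turn_sd_deg = turn_sd_deg), class = "phase_behavior")
}

#' Behaviour parameter sets
#'
#' `diurnal_params()` models a zebrafish-like animal: in the light phase it
#' is almost continuously active at ~6 cm/s; in the dark phase it rests in
#' long quiescence bouts (mean 20 s, so the bulk exceed the 5 s sleep
#' criterion) with brief ~3 cm/s excursions, giving an expected dark-phase
#' mean speed near 0.5 cm/s. `nocturnal_params()` (catfish-like) swaps the
#' two phases. The quiescent state keeps a small positional jitter
#' (`quiescent_speed_cms`) — resting fish hold station, they are not pinned.
#'
#' @param light,dark `phase_behavior` objects.
#' @param tank_cm Tank width and height, cm.
#' @param fps Frame rate (30 by default, the chamber's recording rate).
#' @param quiescent_speed_cms Residual speed while quiescent, cm/s.
#' @return List of class `behavior_params`.
#' @export
behavior_params <- function(light, dark, tank_cm = c(20, 10), fps = 30,
                            quiescent_speed_cms = 0.05) {
  stopifnot(inherits(light, "phase_behavior"),
            inherits(dark, "phase_behavior"),
            all(tank_cm > 0), fps > 0, quiescent_speed_cms >= 0)
  structure(list(light = light, dark = dark, tank_cm = tank_cm, fps = fps,
                 quiescent_speed_cms = quiescent_speed_cms),
            class = "behavior_params")
}

#' @rdname behavior_params
#' @export
diurnal_params <- function(tank_cm = c(20, 10), fps = 30) {
  behavior_params(
    light = phase_behavior(60, 3, 6),
    dark = phase_behavior(4, 20, 3),
    tank_cm = tank_cm, fps = fps)
}

#' @rdname behavior_params
#' @export
nocturnal_params <- function(tank_cm = c(20, 10), fps = 30) {
  behavior_params(
    light = phase_behavior(4, 20, 3),
    dark = phase_behavior(60, 3, 6),
    tank_cm = tank_cm, fps = fps)
}

## alternate exponential dwells across one constant-phase segment; returns
## logical active-state per frame. Memorylessness justifies restarting the
## dwell clock at phase boundaries.
sim_states_segment <- function(n_frames, start_active, pb, fps) {
  out <- logical(n_frames)
  t <- 0
  active <- start_active
  total <- n_frames / fps
  while (t < total) {
    mean_dwell <- if (active) pb$dwell_active_s else pb$dwell_quiescent_s
    dwell <- stats::rexp(1L, rate = 1 / mean_dwell)
    i0 <- floor(t * fps) + 1
    i1 <- min(n_frames, ceiling((t + dwell) * fps))
    if (i1 >= i0) out[i0:i1] <- active
    t <- t + dwell
    active <- !active
  }
  out
}

## fold an unconstrained coordinate into [0, L] (reflecting walls)
reflect_fold <- function(x, L) L - abs(L - (x %% (2 * L)))

#' Simulate ground-truthed fish trajectories
#'
#' Each fish carries its own RNG stream derived from `(seed, fish index)`,
#' so adding fish never perturbs existing trajectories. State switching is a
#' two-state Markov chain with exponential dwell times whose means depend on
#' the light phase at each moment; active motion is a correlated random walk
#' (persistent heading plus wrapped-normal turns, per-frame step =
#' speed/fps) with reflecting tank walls; quiescence is a small isotropic
#' jitter.
#'
#' @param params A [behavior_params()].
#' @param schedule A [light_schedule()] deciding the phase over time.
#' @param n_fish Number of fish.
#' @param duration_s Simulated duration, seconds.
#' @param start_clock_time Clock time (h) at the first frame.
#' @param seed Integer seed.
#' @param tank_id Tank id stamped on the trajectories.
#' @param sub_bounds Optional list (length `n_fish`) of per-fish bounding
#'   boxes `c(x_min, x_max, y_min, y_max)` in cm, to confine fish to
#'   disjoint regions (used by identity-accuracy fixtures).
#' @return List with `trajectories` (list of [trajectory()], cm, tank-local)
#'   and `truth`: per-fish list with `states` (logical active flag per
#'   frame), `drawn_speeds` (cm/s per frame), `phase` (per frame), plus the
#'   realized per-phase mean active speed and quiescent-time fraction.
#' @export
simulate_trajectory <- function(params, schedule = light_schedule(),
                                n_fish = 1L, duration_s = 60,
                                start_clock_time = 12, seed = 1L,
                                tank_id = 1L, sub_bounds = NULL) {
  fps <- params$fps
  n <- max(2L, as.integer(round(duration_s * fps)))
  time_h <- start_clock_time + (seq_len(n) - 1L) / fps / 3600
  phase <- phase_of(time_h, schedule)
  segs <- rle(phase)
  trajectories <- vector("list", n_fish)
  truth <- vector("list", n_fish)

  for (f in seq_len(n_fish)) {
    bounds <- if (is.null(sub_bounds)) c(0, params$tank_cm[1L],
                                         0, params$tank_cm[2L])
              else sub_bounds[[f]]
    W <- bounds[2L] - bounds[1L]; H <- bounds[4L] - bounds[3L]
    if (W <= 0 || H <= 0) stop2("invalid sub_bounds for fish ", f)
    res <- with_seed(derive_seed(seed, (tank_id - 1L) * 1000L + f), {
      ## states, segment by segment
      states <- logical(0)
      pb0 <- if (segs$values[1L] == "light") params$light else params$dark
      p_act0 <- pb0$dwell_active_s /
        (pb0$dwell_active_s + pb0$dwell_quiescent_s)
      cur <- stats::runif(1L) < p_act0
      for (s in seq_along(segs$lengths)) {
        pb <- if (segs$values[s] == "light") params$light else params$dark
        st <- sim_states_segment(segs$lengths[s], cur, pb, fps)
        states <- c(states, st)
        cur <- st[length(st)]
      }
      states <- states[seq_len(n)]
      ## per-frame speeds and headings
      sp_mean <- ifelse(phase == "light", params$light$speed_mean_cms,
                        params$dark$speed_mean_cms)
      sp_sdlog <- ifelse(phase == "light", params$light$speed_sdlog,
                         params$dark$speed_sdlog)
      turn_sd <- ifelse(phase == "light", params$light$turn_sd_deg,
                        params$dark$turn_sd_deg) * pi / 180
      speeds <- numeric(n)
      act <- which(states)
      if (length(act))
        speeds[act] <- stats::rlnorm(length(act),
                                     log(pmax(sp_mean[act], 1e-12)) -
                                       sp_sdlog[act]^2 / 2,
                                     sp_sdlog[act])
      speeds[sp_mean == 0 & states] <- 0
      speeds[!states] <- params$quiescent_speed_cms
      heading <- numeric(n)
      heading[1L] <- stats::runif(1L, 0, 2 * pi)
      turns <- stats::rnorm(n, 0, turn_sd)
      ## quiescent frames redraw heading uniformly (uncorrelated jiggle)
      heading <- cumsum(c(heading[1L], turns[-1L]))
      uq <- which(!states)
      if (length(uq)) heading[uq] <- stats::runif(length(uq), 0, 2 * pi)
      step <- speeds / fps
      x0 <- stats::runif(1L, 0.05 * W, 0.95 * W)
      y0 <- stats::runif(1L, 0.05 * H, 0.95 * H)
      xr <- x0 + cumsum(c(0, (step * cos(heading))[-n]))
      yr <- y0 + cumsum(c(0, (step * sin(heading))[-n]))
      list(states = states, speeds = speeds,
           x = bounds[1L] + reflect_fold(xr, W),
           y = bounds[3L] + reflect_fold(yr, H))
    })
    trajectories[[f]] <- trajectory(cbind(res$x, res$y), fps = fps,
                                    fish_id = f, tank_id = tank_id)
    by_phase <- function(ph) {
      sel <- phase == ph
      list(active_mean_speed = if (any(sel & res$states))
             mean(res$speeds[sel & res$states]) else NA_real_,
           quiescent_fraction = if (any(sel)) mean(!res$states[sel])
                                else NA_real_)
    }
    truth[[f]] <- list(states = res$states, drawn_speeds = res$speeds,
                       phase = phase,
                       light = by_phase("light"), dark = by_phase("dark"),
                       seed = seed)
  }
  list(trajectories = trajectories, truth = truth, phase = phase)
}

#' Rendering parameters
#'
#' @param px_per_cm Pixels per cm; `NULL` (default) takes the layout's
#'   calibration (they must agree if both are given).
#' @param fish_radius_px Rendered fish disk radius, px.
#' @param fish_intensity,background_intensity 8-bit intensities; fish are
#'   dark blobs on a lit background, as seen by a camera over a light box.
#' @param noise_sd Additive Gaussian noise sigma (intensity units).
#' @param artifact `"none"` or `"dark_lines"`: full-width one-pixel dark
#'   rows appearing every `artifact_period` frames at a random height,
#'   emulating camera/LED acquisition stripes.
#' @param artifact_intensity Intensity of artifact rows.
#' @param artifact_period Frames between artifact rows.
#' @param seed Seed for noise and artifact placement.
#' @return List of class `render_params`.
#' @export
render_params <- function(px_per_cm = NULL, fish_radius_px = 4,
                          fish_intensity = 30, background_intensity = 200,
                          noise_sd = 3, artifact = c("none", "dark_lines"),
                          artifact_intensity = 60, artifact_period = 10L,
                          seed = 1L) {
  artifact <- match.arg(artifact)
  stopifnot(fish_intensity >= 0, fish_intensity <= 255,
            background_intensity >= 0, background_intensity <= 255,
            fish_intensity != background_intensity, noise_sd >= 0)
  structure(list(px_per_cm = px_per_cm, fish_radius_px = fish_radius_px,
                 fish_intensity = fish_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, artifact = artifact,
                 artifact_intensity = artifact_intensity,
                 artifact_period = as.integer(artifact_period),
                 seed = as.integer(seed)), class = "render_params")
}

## stamp an anti-aliased disk (coverage-weighted blend towards `value`)
stamp_disk <- function(frame, cx, cy, r, value) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- max(0L, floor(cx - r - 1)); x1 <- min(w - 1L, ceiling(cx + r + 1))
  y0 <- max(0L, floor(cy - r - 1)); y1 <- min(h - 1L, ceiling(cy + r + 1))
  if (x1 < x0 || y1 < y0) return(frame)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  sub <- frame[ys + 1L, xs + 1L, drop = FALSE]
  frame[ys + 1L, xs + 1L] <- sub * (1 - cov) + value * cov
  frame
}

#' Render trajectories to a synthetic video
#'
#' Draws every fish as an anti-aliased dark disk at its position inside its
#' tank ROI, adds Gaussian pixel noise and (optionally) periodic one-pixel
#' dark-line artifact rows. Reproducible from `rp$seed`.
#'
#' @param trajs List of [trajectory()] objects (cm, tank-local coordinates);
#'   `tank_id` selects the ROI in `layout`.
#' @param layout A [tank_layout()] (typically from [default_tank_layout()],
#'   whose `frame_dim` attribute sets the frame size).
#' @param rp A [render_params()].
#' @param frame_dim Frame `c(width, height)` in px; defaults to the layout's
#'   `frame_dim` attribute.
#' @return A [frame_sequence].
#' @export
render_video <- function(trajs, layout, rp = render_params(),
                         frame_dim = NULL) {
  stopifnot(length(trajs) > 0L)
  fd <- frame_dim %||% attr(layout, "frame_dim")
  if (is.null(fd)) stop2("frame_dim required (layout lacks the attribute)")
  w <- as.integer(fd[[1L]]); h <- as.integer(fd[[2L]])
  check_layout_in_frame(layout, w, h)
  ppc <- layout$px_per_cm
  if (!is.null(rp$px_per_cm) && abs(rp$px_per_cm - ppc) > 1e-9)
    stop2("render px_per_cm disagrees with the layout calibration")
  n <- nrow(trajs[[1L]]$positions)
  fps <- trajs[[1L]]$fps
  roi_of <- function(id) layout$tanks[match(id, layout$tanks$tank_id), ]
  ## precompute pixel positions per fish
  px <- lapply(trajs, function(tr) {
    roi <- roi_of(tr$tank_id)
    cbind(roi$x_min + tr$positions[, 1L] * ppc,
          roi$y_min + tr$positions[, 2L] * ppc)
  })
  for (p in px) {
    if (anyNA(p)) stop2("cannot render trajectories with missing positions")
    if (min(p) < -0.5 || max(p[, 1L]) > w - 0.5 || max(p[, 2L]) > h - 0.5)
      stop2("fish position falls outside the frame")
  }
  frames <- with_seed(rp$seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      fr <- matrix(rp$background_intensity, h, w)
      for (f in seq_along(trajs))
        fr <- stamp_disk(fr, px[[f]][i, 1L], px[[f]][i, 2L],
                         rp$fish_radius_px, rp$fish_intensity)
      if (rp$artifact == "dark_lines" && (i - 1L) %% rp$artifact_period == 0L)
        fr[sample.int(h, 1L), ] <- rp$artifact_intensity
      if (rp$noise_sd > 0)
        fr <- fr + stats::rnorm(h * w, 0, rp$noise_sd)
      out[[i]] <- matrix(as.integer(pmin(pmax(round(fr), 0), 255)), h, w)
    }
    out
  })
  frame_sequence(frames, fps = fps)
}

#' Generate a complete ground-truthed circadian study fixture
#'
#' Emulates the chamber protocol: one short video per hour over `hours`
#' hours under a 12:12 schedule, six tanks of three fish by default. Writes
#' `hour_HH.tif` videos (uncompressed multi-page TIFF), a
#' `truth_traj.csv` (per-frame ground-truth positions and states) and
#' `truth_states.csv` (per fish x hour realized summaries), plus
#' `fixture_config.toml` describing layout and schedule.
#'
#' @param profile `"diurnal"` or `"nocturnal"`.
#' @param n_tanks,fish_per_tank Chamber geometry.
#' @param hours Number of hourly intervals (>= 24 recommended for circadian
#'   statistics).
#' @param seed Master seed; every hour/tank/fish derives its own stream.
#' @param out_dir Output directory (created).
#' @param schedule A [light_schedule()]; `recording_duration` sets the video
#'   length per interval.
#' @param fps Frame rate.
#' @param px_per_cm Camera calibration.
#' @param rp A [render_params()].
#' @param write_video If `FALSE`, skip rendering/writing videos (truth CSVs
#'   only) — useful for trajectory-level studies.
#' @param start_clock_time Clock time (h) of the first interval.
#' @return Invisibly, a list with `dir`, `layout`, `schedule`, `hours`,
#'   per-hour video paths, and the in-memory truth tables.
#' @export
make_study_fixture <- function(profile = c("diurnal", "nocturnal"),
                               n_tanks = 6L, fish_per_tank = 3L,
                               hours = 24L, seed = 1L, out_dir,
                               schedule = light_schedule(), fps = 30,
                               px_per_cm = 4, rp = render_params(),
                               write_video = TRUE, start_clock_time = 0) {
  profile <- match.arg(profile)
  params <- if (profile == "diurnal") diurnal_params(fps = fps)
            else nocturnal_params(fps = fps)
  layout <- default_tank_layout(n_tanks, fish_per_tank,
                                px_per_cm = px_per_cm,
                                tank_cm = params$tank_cm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj_rows <- list(); state_rows <- list(); videos <- character(0)
  for (hh in seq_len(hours) - 1L) {
    clock <- start_clock_time + hh
    all_trajs <- list()
    for (tk in seq_len(n_tanks)) {
      sim <- simulate_trajectory(params, schedule, n_fish = fish_per_tank,
                                 duration_s = schedule$recording_duration,
                                 start_clock_time = clock,
                                 seed = derive_seed(seed, hh * 97L + tk),
                                 tank_id = tk)
      all_trajs <- c(all_trajs, sim$trajectories)
      for (f in seq_len(fish_per_tank)) {
        tr <- sim$trajectories[[f]]; tt <- sim$truth[[f]]
        traj_rows[[length(traj_rows) + 1L]] <- data.frame(
          hour = hh, tank_id = tk, fish_id = f,
          frame = seq_len(nrow(tr$positions)) - 1L,
          x_cm = round(tr$positions[, 1L], 5),
          y_cm = round(tr$positions[, 2L], 5),
          active = as.integer(tt$states))
        ph <- sim$phase[1L]
        realized <- if (ph == "light") tt$light else tt$dark
        state_rows[[length(state_rows) + 1L]] <- data.frame(
          hour = hh, tank_id = tk, fish_id = f, phase = ph,
          active_mean_speed = realized$active_mean_speed,
          quiescent_fraction = realized$quiescent_fraction)
      }
    }
    if (write_video) {
      rp_h <- rp
      rp_h$seed <- derive_seed(seed, 50000L + hh)
      vid <- render_video(all_trajs, layout, rp_h)
      path <- file.path(out_dir, sprintf("hour_%02d.tif", hh))
      write_frames(vid, path)
      videos <- c(videos, path)
    }
  }
  truth_traj <- do.call(rbind, traj_rows)
  truth_states <- do.call(rbind, state_rows)
  utils::write.csv(truth_traj, file.path(out_dir, "truth_traj.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_states, file.path(out_dir, "truth_states.csv"),
                   row.names = FALSE)
  write_config(list(
    study = list(profile = profile, hours = hours, seed = seed, fps = fps,
                 start_clock_time = start_clock_time),
    layout = list(px_per_cm = px_per_cm, n_tanks = n_tanks,
                  fish_per_tank = fish_per_tank,
                  tank_cm = params$tank_cm),
    schedule = list(lights_on_hour = schedule$lights_on_hour,
                    lights_off_hour = schedule$lights_off_hour,
                    recording_interval = schedule$recording_interval,
                    recording_duration = schedule$recording_duration)),
    file.path(out_dir, "fixture_config.toml"))
  invisible(list(dir = out_dir, layout = layout, schedule = schedule,
                 hours = hours, videos = videos, truth_traj = truth_traj,
                 truth_states = truth_states, params = params))
}
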