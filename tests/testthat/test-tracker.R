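test_that("estimate_background: static scenes and median robustness", {
  frames <- rep(list(matrix(200L, 20, 20)), 10)
  fs <- frame_sequence(frames, fps = 30)
  expect_equal(estimate_background(fs), matrix(200, 20, 20))

  ## dark disk present at one pixel in < 50% of frames -> floor wins
  frames2 <- frames
  for (i in 1:4) frames2[[i]][10, 10] <- 20L
  fs2 <- frame_sequence(frames2, fps = 30)
  bg <- estimate_background(fs2, 10)
  expect_equal(bg[10, 10], 200)
  expect_error(estimate_background(fs2, 99), "n_samples")
})

test_that("label_components matches the flood-fill oracle", {
  set.seed(21)
  for (rep in 1:8) {
    mask <- matrix(runif(15 * 12) < 0.3, 15)
    want <- brute_components(mask)
    got <- fishrhythm:::label_components(mask)
    expect_equal(length(got$pixels), sum(mask))
    ## same partition: labels agree up to renaming
    if (sum(mask) > 0) {
      w <- want[got$pixels]
      ## labels agree up to renaming: the pairing is a bijection
      expect_equal(length(unique(w)), length(unique(got$labels)))
      expect_equal(length(unique(paste(w, got$labels))),
                   length(unique(w)))
    }
  }
})

test_that("segment_frame recovers rendered disk centroids to < 0.5 px", {
  lay <- one_tank_layout()
  bg <- matrix(200L, 48, 88)
  tr <- trajectory(cbind(4.0, 6.5), fps = 30, tank_id = 1)  # (20, 30) px
  vid <- render_video(list(tr), lay, render_params(noise_sd = 0))
  det <- segment_frame(vid$frames[[1]], bg, lay)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 20), 0.5)
  expect_lt(abs(det$y - 30), 0.5)

  ## frame identical to background: no detections
  expect_equal(nrow(segment_frame(bg, bg, lay)), 0L)

  ## two disks, expected two fish
  lay2 <- one_tank_layout(fish = 2L)
  tr2 <- trajectory(cbind(14.0, 6.5), fps = 30, tank_id = 1)
  vid2 <- render_video(list(tr, tr2), lay2, render_params(noise_sd = 0))
  expect_equal(nrow(segment_frame(vid2$frames[[1]], bg, lay2)), 2L)
})

test_that("segmentation is invariant to a shared brightness offset", {
  lay <- one_tank_layout()
  bg <- matrix(180L, 48, 88)
  tr <- trajectory(cbind(10, 5), fps = 30, tank_id = 1)
  vid <- render_video(list(tr), lay,
                      render_params(noise_sd = 0,
                                    background_intensity = 180))
  d1 <- segment_frame(vid$frames[[1]], bg, lay)
  d2 <- segment_frame(vid$frames[[1]] + 40L, bg + 40L, lay)
  expect_equal(d1, d2)
})

test_that("assign_detections finds the minimum-cost assignment", {
  set.seed(22)
  for (rep in 1:10) {
    nt <- sample(1:4, 1); nd <- sample(1:4, 1)
    cost <- matrix(runif(nt * nd, 0, 10), nt, nd)
    got <- fishrhythm:::assign_detections(cost)
    ## brute force over all injective assignments
    best <- Inf; bestA <- rep(NA_integer_, nt)
    cols <- seq_len(nd)
    rec <- function(i, used, acc, cur) {
      if (i > nt) { if (acc < best) { best <<- acc; bestA <<- cur }; return() }
      rec(i + 1L, used, acc + 1e8, c(cur, NA))       # leave row unmatched
      for (j in setdiff(cols, used))
        rec(i + 1L, c(used, j), acc + cost[i, j], c(cur, j))
    }
    rec(1L, integer(0), 0, integer(0))
    tot <- function(a) sum(ifelse(is.na(a), 1e8, cost[cbind(seq_len(nt),
                                                            a)]))
    expect_equal(tot(got), tot(bestA), tolerance = 1e-12)
  }
})

test_that("link_tracks: exact reproduction, interpolation, degenerate tanks", {
  lay <- one_tank_layout()
  ## one fish detected every frame: trajectory == detections (cm)
  det <- data.frame(frame_index = 0:9, tank_id = 1,
                    x = 4 + (0:9) * 2, y = 24, area = 20)
  trs <- link_tracks(det, lay, n_frames = 10, fps = 30)
  expect_length(trs, 1L)
  expect_equal(trs[[1]]$positions[, 1], (det$x - 4) / 4)
  expect_equal(trs[[1]]$n_interpolated, 0L)

  ## missing middle detection between (10,10) and (12,10) cm -> (11,10)
  lay2 <- default_tank_layout(1, 1, px_per_cm = 1, tank_cm = c(30, 20),
                              ncol = 1)
  det2 <- data.frame(frame_index = c(0, 2), tank_id = 1,
                     x = c(14, 16), y = 14, area = 20)  # cm+4px margin
  trs2 <- link_tracks(det2, lay2, n_frames = 3, fps = 30)
  expect_equal(trs2[[1]]$positions[2, ], c(11, 10), ignore_attr = TRUE)
  expect_equal(trs2[[1]]$n_interpolated, 1L)

  ## no detections at all: warning + all-missing
  expect_warning(trs3 <- link_tracks(det[0, ], lay, n_frames = 5, fps = 30),
                 "no detections")
  expect_true(all(is.na(trs3[[1]]$positions)))

  ## long gaps hold the last position
  det4 <- data.frame(frame_index = c(0, 20), tank_id = 1,
                     x = c(10, 60), y = 24, area = 20)
  trs4 <- link_tracks(det4, lay, n_frames = 21, fps = 30, max_gap = 5)
  expect_equal(trs4[[1]]$positions[10, 1], (10 - 4) / 4)  # held, not interp
  expect_equal(trs4[[1]]$n_interpolated, 0L)
})

test_that("trajectory length always equals the video frame count", {
  lay <- one_tank_layout(fish = 2L)
  set.seed(23)
  det <- data.frame(frame_index = sort(sample(0:29, 40, TRUE)), tank_id = 1,
                    x = runif(40, 5, 80), y = runif(40, 5, 40), area = 20)
  trs <- suppressWarnings(link_tracks(det, lay, n_frames = 30, fps = 30))
  expect_length(trs, 2L)
  for (tr in trs) expect_equal(nrow(tr$positions), 30L)
})

test_that("calibrate scales positions and round-trips", {
  tr <- trajectory(cbind(c(30, 45), c(60, 15)), fps = 30)
  expect_equal(calibrate(tr, 15)$positions,
               cbind(c(2, 3), c(4, 1)), ignore_attr = TRUE)
  expect_equal(calibrate(tr, 1)$positions, tr$positions)
  expect_equal(calibrate(calibrate(tr, 15), 1 / 15)$positions, tr$positions)
  expect_error(calibrate(tr, 0), "px_per_cm")
})

test_that("two never-approaching fish keep their identities end to end", {
  lay <- one_tank_layout(fish = 2L)
  bp <- diurnal_params()
  sb <- list(c(0.5, 8.5, 0.5, 9.5), c(11.5, 19.5, 0.5, 9.5))
  sim <- simulate_trajectory(bp, light_schedule(), n_fish = 2,
                             duration_s = 8, start_clock_time = 12,
                             seed = 31, tank_id = 1, sub_bounds = sb)
  vid <- render_video(sim$trajectories, lay, render_params(noise_sd = 0))
  trk <- track_video(vid, lay)
  err <- sapply(1:2, function(f) {
    d <- sapply(1:2, function(g)
      mean(sqrt(rowSums((trk[[f]]$positions -
                           sim$trajectories[[g]]$positions)^2))))
    d
  })
  ## each track matches exactly one truth fish everywhere (no swaps)
  best <- apply(err, 2, which.min)
  expect_setequal(best, 1:2)
  for (f in 1:2) {
    tt <- sim$trajectories[[best[f]]]
    frame_err <- sqrt(rowSums((trk[[f]]$positions - tt$positions)^2))
    expect_true(all(frame_err * lay$px_per_cm < 2))   # never jumps to other
    expect_lt(mean(frame_err) * lay$px_per_cm, 0.5)
  }
})

test_that("trajectory CSV round-trips through the idTracker-style schema", {
  tr1 <- trajectory(cbind(1:5, 5:1), fps = 30, fish_id = 1L, tank_id = 2L)
  tr2 <- trajectory(cbind(2:6, rep(3, 5)), fps = 30, fish_id = 2L,
                    tank_id = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(list(tr1, tr2), path)
  back <- read_trajectories(path, fps = 30)
  expect_length(back, 2L)
  expect_equal(back[[1]]$positions, tr1$positions, ignore_attr = TRUE)
  expect_equal(back[[2]]$positions, tr2$positions, ignore_attr = TRUE)
})
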