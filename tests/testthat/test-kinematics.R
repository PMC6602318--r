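test_that("step_speeds matches the per-step Euclidean oracle", {
  set.seed(41)
  p <- matrix(runif(200), ncol = 2)
  v <- step_speeds(p, fps = 30)
  want <- sapply(1:(nrow(p) - 1), function(i)
    sqrt(sum((p[i + 1, ] - p[i, ])^2)) * 30)
  expect_equal(v, want)
  expect_equal(sum(v) / 30,
               sum(sqrt(rowSums(diff(p)^2))))     # total distance identity
  expect_true(all(step_speeds(matrix(1, 5, 2), fps = 30) == 0))
  ## 1 cm steps at 30 fps -> 30 cm/s everywhere
  expect_equal(step_speeds(cbind(0:9, 0), fps = 30), rep(30, 9))
  expect_error(step_speeds(matrix(1, 1, 2), fps = 30), "2 positions")
})

test_that("turning_angles: collinear, right angle, hexagon, undefined", {
  expect_equal(turning_angles(rbind(c(0, 0), c(1, 0), c(2, 0))), 0)
  expect_equal(turning_angles(rbind(c(0, 0), c(1, 0), c(1, 1))), 90)
  expect_equal(turning_angles(rbind(c(0, 0), c(1, 0), c(1, -1))), -90)
  hexa <- ngon_path(6, 1)
  expect_equal(abs(turning_angles(hexa)), rep(60, 6))
  ## zero-length middle segment -> undefined angles
  p <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))
  expect_true(all(is.na(turning_angles(p)[1:2])))
})

test_that("regular n-gon closed form: meandering = 360 / (n s) deg/cm", {
  s <- summarize_kinematics(trajectory(ngon_path(36, 0.5), fps = 30))
  expect_equal(s$meandering, 20, tolerance = 1e-10)
  expect_equal(s$total_distance, 18, tolerance = 1e-10)
  ## straight line: meandering and angular velocity are 0
  st <- summarize_kinematics(trajectory(cbind(0:10, 0), fps = 30))
  expect_equal(st$meandering, 0)
  expect_equal(st$average_angular_velocity, 0)
})

test_that("endpoint invariances: scaling, rigid motion, time reversal", {
  set.seed(42)
  p <- apply(matrix(rnorm(60, sd = 0.5), ncol = 2), 2, cumsum)
  base <- summarize_kinematics(trajectory(p, fps = 30))
  ## spatial scaling by k
  k <- 2.5
  sc <- summarize_kinematics(trajectory(p * k, fps = 30))
  expect_equal(sc$total_distance, base$total_distance * k)
  expect_equal(sc$average_speed, base$average_speed * k)
  expect_equal(sc$meandering, base$meandering / k)
  expect_equal(sc$average_angular_velocity, base$average_angular_velocity)
  ## rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pr <- sweep(p %*% t(R), 2, c(3, -1), "+")
  rot <- summarize_kinematics(trajectory(pr, fps = 30))
  for (f in c("total_distance", "average_speed", "average_angular_velocity",
              "meandering", "freezing_ratio", "rapid_ratio"))
    expect_equal(rot[[f]], base[[f]])
  ## time reversal
  rev <- summarize_kinematics(trajectory(p[nrow(p):1, ], fps = 30))
  for (f in c("total_distance", "average_speed", "average_angular_velocity",
              "meandering"))
    expect_equal(rev[[f]], base[[f]])
})

test_that("freezing/swimming/rapid ratios partition every trajectory", {
  set.seed(43)
  for (rep in 1:10) {
    p <- apply(matrix(rnorm(40, sd = runif(1, 0.01, 1)), ncol = 2), 2,
               cumsum)
    s <- summarize_kinematics(trajectory(p, fps = 30))
    expect_equal(s$freezing_ratio + s$swimming_ratio + s$rapid_ratio, 1)
    expect_true(all(c(s$freezing_ratio, s$swimming_ratio, s$rapid_ratio,
                      s$sleep_time_fraction) >= 0))
    expect_true(all(c(s$freezing_ratio, s$swimming_ratio, s$rapid_ratio,
                      s$sleep_time_fraction) <= 1))
  }
})

test_that("sleep bouts follow the strict over-5-s rule", {
  cfg <- kinematics_config()
  fast <- rep(5, 300)
  expect_equal(nrow(detect_sleep_bouts(fast, 30, cfg)$bouts), 0L)

  ## 6 s of stillness at 30 fps inside fast swimming: exactly 1 bout, 180
  v <- c(rep(5, 100), rep(0, 180), rep(5, 100))
  b <- detect_sleep_bouts(v, 30, cfg)
  expect_equal(nrow(b$bouts), 1L)
  expect_equal(b$bouts$end_step - b$bouts$start_step + 1L, 180L)
  expect_equal(b$sleep_time_fraction, 180 / length(v))

  ## 4 s is below the minimum; exactly 5 s is not *over* 5 s
  expect_equal(nrow(detect_sleep_bouts(c(rep(5, 50), rep(0, 120), rep(5, 50)),
                                       30, cfg)$bouts), 0L)
  expect_equal(nrow(detect_sleep_bouts(c(rep(5, 50), rep(0, 150), rep(5, 50)),
                                       30, cfg)$bouts), 0L)
  expect_equal(nrow(detect_sleep_bouts(c(rep(5, 50), rep(0, 151), rep(5, 50)),
                                       30, cfg)$bouts), 1L)
})

test_that("freezing_ratio recovers the generator's quiescent fraction", {
  bp <- diurnal_params()
  sim <- simulate_trajectory(bp, light_schedule(), n_fish = 1,
                             duration_s = 600, start_clock_time = 0,
                             seed = 44)
  s <- summarize_kinematics(sim$trajectories[[1]])
  truth_q <- mean(!sim$truth[[1]]$states)
  expect_lt(abs(s$freezing_ratio - truth_q), 0.05)
})

test_that("degenerate and invalid inputs are handled", {
  expect_error(summarize_kinematics(trajectory(matrix(0, 2, 2), fps = 30)),
               "3 positions")
  s <- summarize_kinematics(trajectory(matrix(1, 10, 2), fps = 30))
  expect_true(s$degenerate)
  expect_equal(s$meandering, 0)
  tr <- trajectory(rbind(c(0, 0), c(NA, NA), c(1, 1)), fps = 30)
  expect_error(summarize_kinematics(tr), "missing")
  expect_error(kinematics_config(v_freeze = 5, v_rapid = 2), "v_freeze")
})
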