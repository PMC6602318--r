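test_that("profiles are phase-labelled by the half-open 12:12 convention", {
  sched <- light_schedule(8, 20)
  prof <- assemble_profile(rnorm(24), sched, start_clock_time = 0)
  expect_equal(sum(prof$phase == "light"), 12L)
  expect_equal(sum(prof$phase == "dark"), 12L)
  expect_equal(prof$phase[prof$time_h == 8], "light")   # lights-on boundary
  expect_equal(prof$phase[prof$time_h == 20], "dark")   # lights-off boundary
  expect_equal(nrow(assemble_profile(numeric(0), sched)), 0L)
  ## schedule wrapping midnight
  swrap <- light_schedule(20, 8)
  pw <- phase_of(c(20, 23, 0, 7.9, 8, 19.9), swrap)
  expect_equal(pw, c("light", "light", "light", "light", "dark", "dark"))
})

test_that("phase_means classifies diurnal / nocturnal / ambiguous", {
  sched <- light_schedule()
  prof <- assemble_profile(c(rep(1, 8), rep(10, 12), rep(1, 4)), sched, 0)
  expect_equal(phase_means(prof)$classification, "diurnal")
  prof2 <- assemble_profile(c(rep(10, 8), rep(1, 12), rep(10, 4)), sched, 0)
  expect_equal(phase_means(prof2)$classification, "nocturnal")
  prof3 <- assemble_profile(rep(3, 24), sched, 0)
  expect_equal(phase_means(prof3)$classification, "ambiguous")
  lonely <- assemble_profile(1:3, light_schedule(), 9)  # light only
  expect_error(phase_means(lonely), "both phases")
})

test_that("minmax_normalize: contract, idempotence, affine invariance", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 50, 100))
  expect_equal(minmax_normalize(c(0, 25, 100)), c(0, 25, 100))
  set.seed(51)
  for (rep in 1:10) {
    x <- rnorm(sample(3:30, 1))
    nx <- minmax_normalize(x)
    expect_equal(min(nx), 0)
    expect_equal(max(nx), 100)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(minmax_normalize(a * x + b), nx)
  }
  expect_error(minmax_normalize(rep(2, 5)), "constant")
  expect_error(minmax_normalize(3), "at least 2")
})

test_that("spearman_test matches exact enumeration and handles ties", {
  expect_equal(spearman_test(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearman_test(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  ## against R's exact method (no ties), several n
  set.seed(52)
  for (n in c(4, 5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    s <- spearman_test(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(s$rho, unname(ct$estimate))
    expect_equal(s$p_value, ct$p.value, tolerance = 1e-12)
  }
  ## with ties: against an in-test brute-force enumerator
  x <- c(1, 1, 2, 3, 4); y <- c(2, 3, 3, 5, 1)
  s <- spearman_test(x, y)
  rx <- rank(x); ry <- rank(y)
  rhos <- sapply(all_perms(seq_along(y)), function(p) cor(rx, ry[p]))
  expect_equal(s$p_value, mean(abs(rhos) >= abs(s$rho) - 1e-12))
  ## invariance under strictly monotone transforms
  a <- rexp(7); b <- rnorm(7)
  expect_equal(spearman_test(a, b)$rho, spearman_test(log(a), b^3)$rho)
  expect_error(spearman_test(1:3, 1:4), "lengths")
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("welch_t agrees with stats::t.test and degenerates correctly", {
  set.seed(53)
  x <- rnorm(10); y <- rnorm(12, 1, 2)
  w <- welch_t(x, y)
  tt <- t.test(x, y)
  expect_equal(w$statistic, unname(tt$statistic))
  expect_equal(w$degrees_of_freedom, unname(tt$parameter))
  expect_equal(w$p_value, tt$p.value)
  ## identical samples: t = 0, p = 1
  w0 <- welch_t(x, x)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  ## equal n: Welch statistic equals the pooled-variance statistic
  y2 <- rnorm(10)
  expect_equal(welch_t(x, y2)$statistic,
               unname(t.test(x, y2, var.equal = TRUE)$statistic))
  expect_error(welch_t(1, 1:5), "size")
})

test_that("welch p agrees with a permutation null on exchangeable data", {
  set.seed(54)
  x <- rnorm(10); y <- rnorm(10)
  w <- welch_t(x, y)
  pooled <- c(x, y)
  reps <- 20000
  tstar <- replicate(reps, {
    idx <- sample(20, 10)
    welch_t(pooled[idx], pooled[-idx])$statistic
  })
  p_perm <- mean(abs(tstar) >= abs(w$statistic))
  mcse <- 3 * sqrt(p_perm * (1 - p_perm) / reps) + 0.02
  expect_lt(abs(w$p_value - p_perm), mcse)
})

test_that("dunnett_test: two-group equivalence, null behaviour, ordering", {
  set.seed(55)
  x <- rnorm(12); y <- rnorm(12, 0.8)
  d <- dunnett_test(list(x, y), control_index = 1, mc_reps = 40000,
                    seed = 9)[[1]]
  ## no multiplicity: matches the plain pooled two-sample test
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(abs(d$statistic), abs(unname(tt$statistic)), tolerance = 1e-9)
  expect_equal(d$p_value, tt$p.value, tolerance = 0.02)

  ## three identical large groups: all adjusted p near 1
  g <- rep(list(rnorm(200)), 3)
  g <- lapply(g, function(z) z - mean(z))
  d3 <- dunnett_test(g, mc_reps = 5000, seed = 10)
  expect_true(all(sapply(d3, `[[`, "p_value") > 0.9))

  ## adjusted p never undercuts the marginal p of the same statistic
  set.seed(56)
  for (rep in 1:5) {
    gg <- lapply(1:4, function(i) rnorm(8, mean = runif(1, 0, 1)))
    dd <- dunnett_test(gg, mc_reps = 4000, seed = rep)
    for (r in dd) expect_gte(r$p_value, r$p_unadjusted - 0.02)
  }
  expect_error(dunnett_test(list(1:5)), "2 groups")
  expect_error(dunnett_test(list(1:5, 1:5), control_index = 7), "range")
})

test_that("determinism: same seed gives identical Dunnett p-values", {
  g <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  p1 <- sapply(dunnett_test(g, mc_reps = 2000, seed = 77), `[[`, "p_value")
  p2 <- sapply(dunnett_test(g, mc_reps = 2000, seed = 77), `[[`, "p_value")
  expect_identical(p1, p2)
})
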