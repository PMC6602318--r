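## Circadian profile assembly and the statistical toolbox used to compare
## light/dark phases and to cross-validate the two locomotion backends.

#' Light-dark schedule
#'
#' @param lights_on_hour,lights_off_hour Clock hours in `[0, 24)`; the light
#'   phase is the half-open interval `[on, off)` modulo 24. Defaults give the
#'   standard LD 12:12 photo-regimen (lights on 08:00-20:00).
#' @param recording_interval Minutes between recordings (default 60: one
#'   recording per hour).
#' @param recording_duration Seconds recorded per interval (default 60).
#' @return List of class `light_schedule`.
#' @export
light_schedule <- function(lights_on_hour = 8, lights_off_hour = 20,
                           recording_interval = 60,
                           recording_duration = 60) {
  if (lights_on_hour < 0 || lights_on_hour >= 24 ||
      lights_off_hour < 0 || lights_off_hour >= 24)
    stop2("schedule hours must lie in [0, 24)")
  if (lights_on_hour == lights_off_hour)
    stop2("lights_on_hour and lights_off_hour must differ")
  structure(list(lights_on_hour = lights_on_hour,
                 lights_off_hour = lights_off_hour,
                 recording_interval = recording_interval,
                 recording_duration = recording_duration),
            class = "light_schedule")
}

#' Phase (light/dark) of a clock time under a schedule
#'
#' @param time_h Clock times in hours (any real; reduced mod 24).
#' @param schedule A [light_schedule()].
#' @return Character vector, `"light"` or `"dark"`.
#' @export
phase_of <- function(time_h, schedule) {
  t <- time_h %% 24
  on <- schedule$lights_on_hour; off <- schedule$lights_off_hour
  lit <- if (on < off) t >= on & t < off else t >= on | t < off
  ifelse(lit, "light", "dark")
}

#' Assemble per-interval metrics into a circadian profile
#'
#' Labels each sample light or dark according to its clock time (half-open
#' at both transitions: a sample exactly at lights-on is light, exactly at
#' lights-off is dark).
#'
#' @param values Per-interval metric values, in temporal order.
#' @param schedule A [light_schedule()].
#' @param start_clock_time Clock time (hours) of the first sample.
#' @param metric_name,subject_id Labels stored with the profile.
#' @return data.frame of class `circadian_profile` with columns
#'   `subject_id, metric, time_h, phase, value`.
#' @export
assemble_profile <- function(values, schedule, start_clock_time = 0,
                             metric_name = "activity", subject_id = "s1") {
  n <- length(values)
  t <- start_clock_time + (seq_len(n) - 1L) * schedule$recording_interval / 60
  df <- data.frame(subject_id = rep_len(subject_id, n),
                   metric = rep_len(metric_name, n),
                   time_h = t, phase = phase_of(t, schedule),
                   value = as.numeric(values))
  class(df) <- c("circadian_profile", "data.frame")
  df
}

#' Phase means and diurnal/nocturnal classification
#'
#' @param profile A `circadian_profile` (needs >= 1 sample in each phase).
#' @return List with `light_mean`, `dark_mean` and `classification`
#'   (`"diurnal"` if light mean strictly exceeds dark mean, `"nocturnal"` if
#'   strictly less, `"ambiguous"` on an exact tie).
#' @export
phase_means <- function(profile) {
  lm_ <- profile$value[profile$phase == "light"]
  dm_ <- profile$value[profile$phase == "dark"]
  if (length(lm_) == 0L || length(dm_) == 0L)
    stop2("profile must contain samples in both phases")
  lmu <- mean(lm_); dmu <- mean(dm_)
  list(light_mean = lmu, dark_mean = dmu,
       classification = if (lmu > dmu) "diurnal"
                        else if (lmu < dmu) "nocturnal" else "ambiguous")
}

#' Min-max normalization to a 0-100% scale
#'
#' Rescales a series so its smallest value maps to 0% and its largest to
#' 100% — the convention used to put the two backends' otherwise
#' incommensurable activity units on a common scale before comparison.
#'
#' @param values Numeric vector, length >= 2, with `max > min`.
#' @return Vector in `[0, 100]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2L) stop2("need at least 2 values to normalize")
  lo <- min(values); hi <- max(values)
  if (hi <= lo)
    stop2("degenerate normalization: series is constant (min == max)")
  (values - lo) / (hi - lo) * 100
}

#' Spearman rank correlation with exact small-sample p
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' exact — computed by full enumeration of all n! rank permutations — for
#' `n <= 8`, and uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df otherwise.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop2("x and y lengths differ")
  if (n < 3L) stop2("need n >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop2("correlation undefined for a constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Welch two-sample t test (unequal variances)
#'
#' Unpaired t statistic with Welch's correction:
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with Satterthwaite
#' degrees of freedom; two-sided p.
#'
#' @param x,y Samples, each of size >= 2 with positive variance (at least
#'   one must have positive variance).
#' @param label Comparison label carried into the result.
#' @return `test_result` list: `test_name`, `statistic`,
#'   `degrees_of_freedom`, `p_value`, `comparison`.
#' @export
welch_t <- function(x, y, label = "x vs y") {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop2("each sample needs size >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 <= 0) stop2("both samples have zero variance")
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  structure(list(test_name = "Welch t", statistic = tstat,
                 degrees_of_freedom = df,
                 p_value = 2 * stats::pt(-abs(tstat), df = df),
                 comparison = label), class = "test_result")
}

#' Dunnett many-to-one comparisons via seeded Monte Carlo
#'
#' Compares every group mean against a control using pooled-variance t
#' statistics, with the family-wise adjusted p for group i computed as the
#' Monte Carlo probability, under equal means and normality with the pooled
#' variance, that the maximum absolute statistic across the family exceeds
#' `|t_i|`. The t statistics are pivotal, so the null draw is exact up to
#' Monte Carlo error; `mc_reps` and `seed` make results reproducible.
#'
#' @param groups List of numeric samples (>= 2 groups, each size >= 2).
#' @param control_index Index of the control group.
#' @param mc_reps Monte Carlo replicates (default 1e5).
#' @param seed RNG seed for the null draw.
#' @param labels Optional group labels.
#' @return List of `test_result`, one per non-control group, each with the
#'   extra fields `p_unadjusted` (marginal p of the same pooled statistic)
#'   and `statistic` (pooled-variance t vs control).
#' @export
dunnett_test <- function(groups, control_index = 1L, mc_reps = 1e5,
                         seed = 1L, labels = NULL) {
  k <- length(groups)
  if (k < 2L) stop2("need at least 2 groups")
  if (control_index < 1L || control_index > k)
    stop2("control_index out of range")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop2("each group needs size >= 2")
  labels <- labels %||% paste0("group", seq_len(k))
  N <- sum(ns)
  df <- N - k
  s2 <- sum(vapply(groups, function(g) (length(g) - 1) * stats::var(g),
                   0)) / df
  mu <- vapply(groups, mean, 0)
  others <- setdiff(seq_len(k), control_index)
  n0 <- ns[control_index]
  tobs <- (mu[others] - mu[control_index]) /
    sqrt(s2 * (1 / ns[others] + 1 / n0))

  maxT <- with_seed(seed, {
    z <- matrix(stats::rnorm(mc_reps * N), nrow = mc_reps)
    ends <- cumsum(ns); starts <- ends - ns + 1L
    gm <- sapply(seq_len(k), function(j)
      rowMeans(z[, starts[j]:ends[j], drop = FALSE]))
    gss <- sapply(seq_len(k), function(j) {
      blk <- z[, starts[j]:ends[j], drop = FALSE]
      rowSums(blk^2) - ns[j] * gm[, j]^2
    })
    s2r <- rowSums(gss) / df
    tmat <- sapply(others, function(j)
      (gm[, j] - gm[, control_index]) /
        sqrt(s2r * (1 / ns[j] + 1 / n0)))
    if (is.null(dim(tmat))) tmat <- matrix(tmat, ncol = 1L)
    apply(abs(tmat), 1L, max)
  })

  lapply(seq_along(others), function(i) {
    structure(list(
      test_name = "Dunnett (Monte Carlo)",
      statistic = tobs[i],
      degrees_of_freedom = df,
      p_value = (sum(maxT >= abs(tobs[i])) + 1) / (mc_reps + 1),
      p_unadjusted = 2 * stats::pt(-abs(tobs[i]), df = df),
      comparison = paste(labels[others[i]], "vs", labels[control_index])),
      class = "test_result")
  })
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> %s: statistic %.4g, df %.4g, p %.4g\n", x$test_name,
              x$comparison, x$statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Cross-validate the two locomotion backends on matched profiles
#'
#' Min-max-normalizes the two per-interval series (pixel activity and
#' trajectory-derived speed), then reports their Spearman correlation — the
#' agreement statistic used to establish that the cheap frame-differencing
#' readout tracks the trajectory-based one.
#'
#' @param activity Per-interval pixel-activity values.
#' @param speed Per-interval (tank-mean) speed values, same length/order.
#' @return List with `rho`, `p_value`, and the two normalized series.
#' @export
cross_validate_backends <- function(activity, speed) {
  na <- minmax_normalize(activity)
  ns <- minmax_normalize(speed)
  sp <- spearman_test(na, ns)
  list(rho = sp$rho, p_value = sp$p_value,
       activity_norm = na, speed_norm = ns)
}
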