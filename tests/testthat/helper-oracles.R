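# Independent oracles and small fixture builders used across the suite.

hex_to_file <- function(hex, path) {
  writeBin(as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                   seq(2, nchar(hex), 2)), 16L)), path)
  path
}

# recursive permutation enumerator, independent of the package's generator
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# brute-force per-pixel changed-count oracle
brute_change_count <- function(a, b, thr) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (abs(a[i, j] - b[i, j]) > thr) n <- n + 1L
  n
}

# queue flood-fill connected components oracle (8-connectivity)
brute_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); cur <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1L] + di; jj <- p[2L] + dj
        if (ii >= 1L && ii <= h && jj >= 1L && jj <= w &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# single-tank layout helper: one ROI covering [4, 4+w) x [4, 4+h) px
one_tank_layout <- function(tank_w_cm = 20, tank_h_cm = 10, px_per_cm = 4,
                            fish = 1L) {
  default_tank_layout(n_tanks = 1L, fish_per_tank = fish,
                      px_per_cm = px_per_cm,
                      tank_cm = c(tank_w_cm, tank_h_cm), ncol = 1L)
}

# regular n-gon of side s traversed once, starting and ending at an edge
# midpoint, so the path covers distance n*s and turns through the full 360
# degrees (n turns of 360/n each)
ngon_path <- function(n, s) {
  ang <- c(2 * pi / n * (0:(n - 1)), 0)
  len <- c(s / 2, rep(s, n - 1), s / 2)
  rbind(c(0, 0), cbind(cumsum(len * cos(ang)), cumsum(len * sin(ang))))
}
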