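# Independent brute-force correlator: explicit loops over frame pairs,
# no shared code with the package implementation.
brute_sums <- function(m, lag) {
  np <- ncol(m) - lag
  g2 <- numeric(nrow(m))
  ifv <- numeric(nrow(m))
  ipv <- numeric(nrow(m))
  for (p in seq_len(nrow(m))) {
    acc <- 0
    for (t in seq_len(np)) acc <- acc + m[p, t] * m[p, t + lag]
    g2[p] <- acc / np
    ifv[p] <- sum(m[p, 1:np]) / np
    ipv[p] <- sum(m[p, (lag + 1):ncol(m)]) / np
  }
  list(g2 = g2, if_ = ifv, ip = ipv)
}

# non-overlapping block means of width 2 (trailing odd frame dropped)
bin_by_two <- function(m) {
  t2 <- ncol(m) %/% 2
  out <- matrix(0, nrow(m), t2)
  for (b in seq_len(t2)) out[, b] <- (m[, 2 * b - 1] + m[, 2 * b]) / 2
  out
}

# photon_events wrapping a dense matrix on a single-ring q map
events_on_ring <- function(m, q = 0.05, frame_rate = 52000) {
  as_photon_events(m, frame_rate_hz = frame_rate,
                   pixel_q = rep(q, nrow(m)))
}

# ensemble plateau of g2 - 1 with an empirical standard error from
# independent pixel groups
plateau_with_se <- function(acc, n_lags = 5, n_groups = 20) {
  ord <- order(acc$lags$lag_frames)[seq_len(n_lags)]
  npx <- nrow(acc$pixels)
  grp <- rep(seq_len(n_groups), length.out = npx)
  vals <- vapply(seq_len(n_groups), function(g) {
    idx <- which(grp == g)
    mean(colMeans(acc$g2_sum[idx, ord, drop = FALSE]) /
           (colMeans(acc$if_sum[idx, ord, drop = FALSE]) *
              colMeans(acc$ip_sum[idx, ord, drop = FALSE]))) - 1
  }, numeric(1))
  list(plateau = mean(vals), se = sd(vals) / sqrt(n_groups))
}
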