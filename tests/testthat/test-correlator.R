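test_that("multi-tau lag ladder has the documented structure", {
  lags <- multitau_lags(64, 52000, channels_per_level = 8)
  expect_equal(lags$lag_frames[lags$level == 0], 1:8)
  expect_equal(lags$lag_s[1], 1 / 52000)        # 19.23 us resolution
  expect_true(all(diff(lags$lag_frames) > 0))
  expect_equal(lags$lag_s, lags$lag_frames / 52000)
  # every level doubles the spacing over channels (c/2, c]
  l1 <- lags[lags$level == 1, ]
  expect_equal(l1$lag_frames, c(10, 12, 14, 16))
  big <- multitau_lags(100000, 52000)
  expect_lte(max(big$lag_frames), 25000)        # n_frames / 4 ceiling
  expect_error(multitau_lags(4, 52000, channels_per_level = 8),
               class = "saxpcs_invalid_input")
})

test_that("a constant stream gives G2 = IF * IP and g2 = 1 at every lag", {
  m <- matrix(3L, 6, 64)
  acc <- correlate_multitau(events_on_ring(m), ring_qmap(0.05, 6))
  expect_identical(acc$g2_sum, acc$if_sum * acc$ip_sum)
  expect_true(all(acc$g2_sum == 9))
  g2 <- normalize_g2(acc)
  expect_true(all(g2$g2 == 1))
  expect_true(all(g2$sigma_g2 == 0))
})

test_that("level-0 sums equal the dense brute-force oracle bit for bit", {
  set.seed(11)
  for (dims in list(c(4, 16), c(16, 64))) {
    m <- matrix(as.numeric(rpois(prod(dims), 1.3)), dims[1], dims[2])
    lags <- multitau_lags(dims[2], 52000, max_lag_frac = 0.6)
    acc <- correlate_multitau(events_on_ring(m), ring_qmap(0.05, dims[1]),
                              lags)
    for (lag in 1:8) {
      i <- which(acc$lags$level == 0 & acc$lags$lag_frames == lag)
      o <- brute_sums(m, lag)
      expect_identical(acc$g2_sum[, i], o$g2)
      expect_identical(acc$if_sum[, i], o$if_)
      expect_identical(acc$ip_sum[, i], o$ip)
    }
  }
})

test_that("level-1 sums equal brute force on the 2-frame-binned stream", {
  set.seed(12)
  m <- matrix(as.numeric(rpois(8 * 128, 2)), 8, 128)
  acc <- correlate_multitau(events_on_ring(m), ring_qmap(0.05, 8))
  mb <- bin_by_two(m)
  l1 <- which(acc$lags$level == 1)
  for (i in l1) {
    ch <- acc$lags$channel[i]
    o <- brute_sums(mb, ch)
    expect_identical(acc$g2_sum[, i], o$g2)
    expect_identical(acc$if_sum[, i], o$if_)
    expect_identical(acc$ip_sum[, i], o$ip)
  }
})

test_that("chunked densification does not change the result", {
  set.seed(13)
  m <- matrix(as.numeric(rpois(10 * 200, 0.5)), 10, 200)
  ev <- events_on_ring(m)
  qm <- ring_qmap(0.05, 10)
  a <- correlate_multitau(ev, qm, chunk_pixels = 3L)
  b <- correlate_multitau(ev, qm, chunk_pixels = 256L)
  expect_identical(a$g2_sum, b$g2_sum)
  expect_identical(a$if_sum, b$if_sum)
})

test_that("averaging accumulators is weight-proportional and exact", {
  set.seed(14)
  qm <- ring_qmap(0.05, 5)
  m1 <- matrix(as.numeric(rpois(5 * 96, 1)), 5, 96)
  m2 <- matrix(as.numeric(rpois(5 * 96, 1)), 5, 96)
  a1 <- correlate_multitau(events_on_ring(m1), qm)
  a2 <- correlate_multitau(events_on_ring(m2), qm)

  self <- average_accumulators(list(a1, a1))
  expect_equal(self$g2_sum, a1$g2_sum)
  expect_equal(self$weights, 2 * a1$weights)
  expect_equal(self$n_repeats, 2L)

  # disjoint-concatenation path: equal-length repeats have equal weights,
  # so the merged sums are the plain mean -- exactly what a gap-
  # concatenated stream with no cross-boundary pairs would give
  avg <- average_accumulators(list(a1, a2))
  expect_equal(avg$g2_sum, (a1$g2_sum + a2$g2_sum) / 2, tolerance = 1e-14)
  expect_equal(avg$if_sum, (a1$if_sum + a2$if_sum) / 2, tolerance = 1e-14)

  a3 <- correlate_multitau(events_on_ring(m1[, 1:64]), qm)
  expect_error(average_accumulators(list(a1, a3)),
               class = "saxpcs_structure_error")
})

test_that("bad-pixel flagging catches injected correlated pixels only", {
  set.seed(15)
  npx <- 60; nfr <- 2000
  m <- matrix(as.numeric(rpois(npx * nfr, 1)), npx, nfr)
  qm <- ring_qmap(0.05, npx)
  acc <- correlate_multitau(events_on_ring(m), qm)
  flags <- flag_bad_pixels(acc)
  expect_lte(mean(flags), 0.01)                  # null false-positive rate

  # inject a pixel with strong slow self-correlation
  bad <- rep(c(4, 0), each = nfr / 2)
  m2 <- m; m2[7, ] <- bad
  acc2 <- correlate_multitau(events_on_ring(m2), qm)
  flags2 <- flag_bad_pixels(acc2)
  expect_true(flags2[7])

  # degenerate spread: identical pixels, none flagged
  m3 <- matrix(2, 20, 64)
  acc3 <- correlate_multitau(events_on_ring(m3), ring_qmap(0.05, 20))
  expect_true(!any(flag_bad_pixels(acc3)))

  # small partitions are skipped with a warning
  m4 <- matrix(as.numeric(rpois(5 * 64, 1)), 5, 64)
  acc4 <- correlate_multitau(events_on_ring(m4), ring_qmap(0.05, 5))
  expect_warning(f4 <- flag_bad_pixels(acc4), "skipped")
  expect_true(!any(f4))
})

test_that("static speckle normalises to the 1/n_modes contrast plateau", {
  cfg <- simulation_config(n_frames = 5000, mean_count_rate = 0.1,
                           ring_spec = tibble::tibble(q = 0.031,
                                                      n_pixels = 600L),
                           seed = 16)
  ev <- static_speckle_sequence(cfg)
  acc <- correlate_multitau(ev, ring_qmap(0.031, 600))
  p <- plateau_with_se(acc)
  expect_lt(abs(p$plateau - 1 / 7), 3 * p$se)
  # g2 of a static sample is tau-independent (no decay trend)
  g2 <- normalize_g2(acc)
  first <- mean(g2$g2[order(g2$lag_frames)][1:5])
  last <- mean(g2$g2[order(g2$lag_frames, decreasing = TRUE)][1:5])
  sem <- mean(g2$sigma_g2, na.rm = TRUE) / sqrt(600)
  expect_lt(abs(first - last), 5 * sem * sqrt(2))
})

test_that("binning before division beats per-pixel g2 in the sparse regime", {
  # A sparse static reference makes the binning-order effect starkest:
  # per-pixel division self-normalises every pixel to ~1 and loses the
  # speckle contrast entirely, while binning G2/IF/IP across the
  # partition first retains the 1 + 1/n_modes plateau.
  cfg <- simulation_config(n_frames = 20000, mean_count_rate = 5e-3,
                           ring_spec = tibble::tibble(q = 0.031,
                                                      n_pixels = 4000L),
                           seed = 17)
  ev <- static_speckle_sequence(cfg)
  acc <- correlate_multitau(ev, ring_qmap(0.031, 4000))
  g2_binned <- normalize_g2(acc)
  den <- acc$if_sum * acc$ip_sum
  pp <- acc$g2_sum / den
  pp[den == 0] <- NA
  g2_pp <- colMeans(pp, na.rm = TRUE)
  ord <- order(acc$lags$lag_frames)[1:5]
  truth <- 1 + 1 / 7
  err_binned <- mean(abs(g2_binned$g2[order(g2_binned$lag_frames)][1:5] - truth))
  err_pp <- mean(abs(g2_pp[ord] - truth))
  expect_lt(err_binned, err_pp)
})

test_that("symmetric normalisation suppresses linear drift", {
  nfr <- 1000
  drift <- 1000 + floor((0:(nfr - 1)) / 10)   # a + bt with bT/a = 0.1
  m <- matrix(drift, 4, nfr, byrow = TRUE)
  acc <- correlate_multitau(events_on_ring(m), ring_qmap(0.05, 4))
  g2 <- normalize_g2(acc)
  expect_lt(max(abs(g2$g2 - 1)), (100 / 1000)^2)
})

test_that("empty-denominator cells are reported missing, not infinite", {
  m <- matrix(0L, 12, 64); m[1, 2] <- 1L   # almost all-dark ring
  acc <- correlate_multitau(events_on_ring(m), ring_qmap(0.05, 12))
  g2 <- suppressWarnings(normalize_g2(acc))
  expect_true(all(is.na(g2$g2) | is.finite(g2$g2)))
})
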