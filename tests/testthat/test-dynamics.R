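test_that("noise-free exponential decay is recovered exactly", {
  lags <- multitau_lags(100000, 52000)
  tau <- lags$lag_s[lags$lag_s < 1.5e-3]
  tau0 <- 1.447e-4                      # 1/(D Q^2) at Q = 0.031 nm^-1
  g2 <- 1 + 0.14 * exp(-2 * tau / tau0)
  f <- fit_single_exponential(tau, g2, beta = 0.14)
  expect_true(f$converged)
  expect_lt(abs(f$tau0 - tau0) / tau0, 1e-8)
  # scale equivariance: halving delays halves tau0
  fh <- fit_single_exponential(tau / 2, g2, beta = 0.14)
  expect_equal(fh$tau0, tau0 / 2, tolerance = 1e-8)
})

test_that("degenerate g2 input is flagged, not fatal", {
  tau <- (1:20) / 52000
  f <- fit_single_exponential(tau, rep(1, 20), beta = 0.14)
  expect_false(f$converged)
  f2 <- fit_single_exponential(tau[1:3], 1 + 0.1 * exp(-tau[1:3]),
                               beta = 0.14)
  expect_false(f2$converged)            # too few points
})

test_that("fit weights are scale-free and beta can be freed", {
  tau <- (1:40) / 52000
  tau0 <- 2e-4
  set.seed(21)
  g2 <- 1 + (1 / 7) * exp(-2 * tau / tau0) + rnorm(40, sd = 2e-3)
  sig <- rep(0.01, 40)
  f1 <- fit_single_exponential(tau, g2, sig, beta = 1 / 7)
  f2 <- fit_single_exponential(tau, g2, sig * 7, beta = 1 / 7)
  expect_equal(f1$tau0, f2$tau0, tolerance = 1e-6)
  ff <- fit_single_exponential(tau, g2, sig, beta = 1 / 7, beta_free = TRUE)
  expect_true(ff$converged)
  expect_lt(abs(ff$beta - 1 / 7), 3 * ff$sigma_beta)
})

test_that("Gamma vs Q^2 through the origin recovers D exactly and honours q_max", {
  d_true <- 7.19e-12
  q <- seq(0.03, 0.09, length.out = 5)
  fits <- tibble::tibble(
    q = q,
    tau0 = 1 / (d_true * (q * 1e9)^2),
    sigma_tau0 = tau0 * 0.01,
    converged = TRUE)
  df <- fit_tau_vs_q(fits, q_max = 0.1)
  expect_equal(df$d, d_true, tolerance = 1e-12)
  # a point beyond q_max changes nothing
  fits2 <- dplyr::bind_rows(fits, tibble::tibble(
    q = 0.2, tau0 = 1e-9, sigma_tau0 = 1e-10, converged = TRUE))
  df2 <- fit_tau_vs_q(fits2, q_max = 0.1)
  expect_equal(df2$d, df$d)
  # permutation invariance
  df3 <- fit_tau_vs_q(fits[sample(5), ], q_max = 0.1)
  expect_equal(df3$d, df$d)
  expect_error(fit_tau_vs_q(fits[1:2, ], q_max = 0.1),
               class = "saxpcs_insufficient_data")
})

test_that("D estimate is nearly unbiased under tau0 noise", {
  d_true <- 7.19e-12
  q <- seq(0.03, 0.12, length.out = 10)
  tau0_true <- 1 / (d_true * (q * 1e9)^2)
  set.seed(30)
  dhat <- replicate(500, {
    tau0 <- tau0_true * (1 + rnorm(10, sd = 0.05))
    fits <- tibble::tibble(q = q, tau0 = tau0,
                           sigma_tau0 = tau0_true * 0.05, converged = TRUE)
    fit_tau_vs_q(fits, q_max = 0.15)$d
  })
  expect_lt(abs(mean(dhat) - d_true) / d_true, 0.01)
})

test_that("Stokes-Einstein inversion reproduces the sample-A radius", {
  fits <- tibble::tibble(
    q = c(0.03, 0.05, 0.07),
    tau0 = 1 / (7.19e-12 * (q * 1e9)^2),
    sigma_tau0 = tau0 * 0.02,
    converged = TRUE)
  df <- fit_tau_vs_q(fits)
  env_a <- environment_spec(279, 1.520e-3, "sample A")
  out <- stokes_einstein_radius(df, env_a)
  expect_equal(out$r_h_nm, 18.7, tolerance = 1e-3)
  expect_equal(out$sigma_r_h_nm / out$r_h_nm, out$sigma_d / out$d)
  # for a fixed D the inferred radius scales inversely with viscosity
  out_c <- stokes_einstein_radius(df, environment_spec(279, 1.672e-3))
  expect_equal(out_c$r_h_nm / out$r_h_nm, 1.520 / 1.672, tolerance = 1e-10)
  # round trip with the generator's forward relation
  d <- diffusivity_from_radius(out$r_h_nm, 279, 1.520e-3)
  expect_equal(d, out$d, tolerance = 1e-12)
  gl <- glance(out)
  expect_equal(gl$r_h_nm, out$r_h_nm)
})

test_that("per-Q fits integrate with g2 results", {
  # two rings with exact exponential g2 written into a g2_result-shaped table
  lags <- multitau_lags(20000, 52000)
  qs <- c(0.031, 0.062)
  d_true <- 7.19e-12
  rows <- purrr::map_dfr(seq_along(qs), function(i) {
    tau0 <- 1 / (d_true * (qs[i] * 1e9)^2)
    tibble::tibble(coarse = i - 1L, q = qs[i], lag_frames = lags$lag_frames,
                   delay_s = lags$lag_s,
                   g2 = 1 + (1 / 7) * exp(-2 * lags$lag_s / tau0),
                   sigma_g2 = 0.01, n_pixels = 100L)
  })
  class(rows) <- c("g2_result", class(tibble::tibble()))
  fits <- fit_g2(rows, beta = 1 / 7)
  expect_equal(nrow(fits), 2)
  expect_true(all(fits$converged))
  expect_equal(fits$tau0, 1 / (d_true * (qs * 1e9)^2), tolerance = 1e-6)
})
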