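#' Stokes-Einstein diffusivity from hydrodynamic radius
#'
#' `D = kT / (6 pi eta R_H)` with `k` the Boltzmann constant.
#'
#' @param r_h_nm Hydrodynamic radius in nm.
#' @param temperature_k Temperature in K.
#' @param viscosity_pa_s Dynamic viscosity in Pa s.
#' @return Diffusivity in m^2 s^-1.
#' @examples
#' diffusivity_from_radius(18.7, 279, 1.520e-3)
#' @export
diffusivity_from_radius <- function(r_h_nm, temperature_k, viscosity_pa_s) {
  if (any(c(r_h_nm, temperature_k, viscosity_pa_s) <= 0)) {
    abort("radius, temperature and viscosity must all be positive.",
          class = "saxpcs_invalid_input")
  }
  k_boltzmann * temperature_k / (6 * pi * viscosity_pa_s * r_h_nm * 1e-9)
}

#' Hydrodynamic radius from diffusivity (inverse Stokes-Einstein)
#'
#' @param d_m2_s Diffusivity in m^2 s^-1.
#' @inheritParams diffusivity_from_radius
#' @return Hydrodynamic radius in nm.
#' @export
radius_from_diffusivity <- function(d_m2_s, temperature_k, viscosity_pa_s) {
  if (any(c(d_m2_s, temperature_k, viscosity_pa_s) <= 0)) {
    abort("diffusivity, temperature and viscosity must all be positive.",
          class = "saxpcs_invalid_input")
  }
  k_boltzmann * temperature_k / (6 * pi * viscosity_pa_s * d_m2_s) * 1e9
}

#' Configuration for the synthetic Brownian speckle generator
#'
#' Describes a simulated small-angle XPCS acquisition: a particle with
#' hydrodynamic radius `true_r_h_nm` diffusing in a solvent at
#' `temperature_k` / `viscosity_pa_s`, observed on detector rings listed in
#' `ring_spec` (one row per ring: `q` in nm^-1, `n_pixels`). Partial
#' coherence is modelled as `n_modes` incoherently summed field modes, so
#' the realised speckle contrast is `beta = 1 / n_modes`; `contrast_beta`
#' is the target value and a warning is raised when `1 / n_modes` differs
#' from it by more than 0.05.
#'
#' @param true_r_h_nm Ground-truth hydrodynamic radius (nm).
#' @param temperature_k Temperature (K).
#' @param viscosity_pa_s Solvent viscosity (Pa s).
#' @param contrast_beta Target speckle contrast (0, 1].
#' @param n_modes Number of coherent modes; defaults to
#'   `round(1 / contrast_beta)`.
#' @param frame_rate_hz Detector frame rate (Hz).
#' @param n_frames Frames per sequence.
#' @param mean_count_rate Mean photons per pixel per frame at the first
#'   (reference) ring.
#' @param ring_spec Data frame with columns `q` (nm^-1, strictly
#'   increasing) and `n_pixels`.
#' @param form_factor Either `"flat"` (all rings share
#'   `mean_count_rate`) or a length-2 numeric `(R0_nm, sigma_r_nm)`; in
#'   the latter case ring count rates follow the polydisperse sphere form
#'   factor normalised to 1 at the reference ring.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(true_r_h_nm = 18.7,
                              temperature_k = 279,
                              viscosity_pa_s = 1.520e-3,
                              contrast_beta = 1 / 7,
                              n_modes = round(1 / contrast_beta),
                              frame_rate_hz = 52000,
                              n_frames = 100000,
                              mean_count_rate = 7e-5,
                              ring_spec = tibble(q = 0.031, n_pixels = 200L),
                              form_factor = "flat",
                              seed = 1L) {
  check_positive_scalar(true_r_h_nm, "true_r_h_nm")
  check_positive_scalar(temperature_k, "temperature_k")
  check_positive_scalar(viscosity_pa_s, "viscosity_pa_s")
  check_positive_scalar(mean_count_rate, "mean_count_rate")
  check_positive_scalar(frame_rate_hz, "frame_rate_hz")
  if (contrast_beta <= 0 || contrast_beta > 1) {
    abort("`contrast_beta` must be in (0, 1].",
          class = "saxpcs_invalid_input")
  }
  n_modes <- as.integer(n_modes)
  if (n_modes < 1L) {
    abort("`n_modes` must be >= 1.", class = "saxpcs_invalid_input")
  }
  if (abs(1 / n_modes - contrast_beta) > 0.05) {
    warn(sprintf(
      "Realised contrast 1/n_modes = %.3f differs from target beta = %.3f by more than 0.05.",
      1 / n_modes, contrast_beta))
  }
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) {
    abort("`n_frames` must be >= 1.", class = "saxpcs_invalid_input")
  }
  ring_spec <- as_tibble(ring_spec)
  if (!all(c("q", "n_pixels") %in% names(ring_spec)) ||
      any(ring_spec$q <= 0) || any(ring_spec$n_pixels < 1)) {
    abort("`ring_spec` needs positive `q` and `n_pixels` columns.",
          class = "saxpcs_invalid_input")
  }
  if (is.numeric(form_factor)) {
    if (length(form_factor) != 2L || form_factor[1] <= 0 ||
        form_factor[2] < 0) {
      abort("Numeric `form_factor` must be (R0_nm > 0, sigma_r_nm >= 0).",
            class = "saxpcs_invalid_input")
    }
  } else if (!identical(form_factor, "flat")) {
    abort('`form_factor` must be "flat" or c(R0_nm, sigma_r_nm).',
          class = "saxpcs_invalid_input")
  }
  structure(
    list(
      true_r_h_nm = true_r_h_nm, temperature_k = temperature_k,
      viscosity_pa_s = viscosity_pa_s, contrast_beta = contrast_beta,
      n_modes = n_modes, frame_rate_hz = frame_rate_hz,
      n_frames = n_frames, mean_count_rate = mean_count_rate,
      ring_spec = ring_spec, form_factor = form_factor,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

new_photon_events <- function(df, n_frames, n_pixels, frame_rate_hz,
                              pixel_q = NULL, config = NULL, seed = NULL) {
  out <- as_tibble(df)
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "n_pixels") <- as.integer(n_pixels)
  attr(out, "frame_rate_hz") <- frame_rate_hz
  attr(out, "pixel_q") <- pixel_q
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("photon_events", class(tibble()))
  out
}

#' @rdname photon_events
#' @export
n_frames <- function(events) attr(events, "n_frames")

#' @rdname photon_events
#' @export
n_pixels <- function(events) attr(events, "n_pixels")

#' @rdname photon_events
#' @export
frame_rate <- function(events) attr(events, "frame_rate_hz")

#' @rdname photon_events
#' @export
pixel_q <- function(events) attr(events, "pixel_q")

#' Sparse photon-event sequences
#'
#' A `photon_events` object is a tibble of sparse detector events with
#' columns `frame` (0-based frame index), `pixel` (0-based pixel index)
#' and `count` (>= 1), sorted by `(frame, pixel)`, plus attributes
#' `n_frames`, `n_pixels`, `frame_rate_hz` and (for ring data) `pixel_q`,
#' the momentum transfer of each pixel. `as_photon_events()` sparsifies a
#' dense pixels-by-frames count matrix; `densify_events()` is its inverse
#' and the two round-trip losslessly.
#'
#' @param counts Dense integer matrix, pixels in rows, frames in columns.
#' @param frame_rate_hz Frame rate in Hz.
#' @param pixel_q Optional per-pixel momentum transfer (nm^-1).
#' @param events A `photon_events` object.
#' @param pixels Optional 0-based pixel indices to densify (defaults to
#'   all pixels).
#' @return `as_photon_events()`: a `photon_events` tibble;
#'   `densify_events()`: a dense matrix with `length(pixels)` rows.
#' @name photon_events
#' @export
as_photon_events <- function(counts, frame_rate_hz = 52000, pixel_q = NULL) {
  np <- nrow(counts)
  nf <- ncol(counts)
  idx <- which(counts > 0)
  # column-major: row (pixel) varies fastest
  px <- (idx - 1L) %% np
  fr <- (idx - 1L) %/% np
  df <- tibble(frame = fr, pixel = px,
               count = as.integer(counts[idx]))
  df <- dplyr::arrange(df, .data$frame, .data$pixel)
  new_photon_events(df, nf, np, frame_rate_hz, pixel_q = pixel_q)
}

#' @rdname photon_events
#' @export
densify_events <- function(events, pixels = NULL) {
  np <- n_pixels(events)
  nf <- n_frames(events)
  if (is.null(pixels)) pixels <- 0:(np - 1L)
  keep <- events$pixel %in% pixels
  rowidx <- match(events$pixel[keep], pixels)
  m <- matrix(0, length(pixels), nf)
  m[cbind(rowidx, events$frame[keep] + 1L)] <- events$count[keep]
  m
}

# One chunk of mode-summed Ornstein-Uhlenbeck speckle intensity.
# Returns an n_frames x p matrix with unit mean. `a` is the per-frame
# field autocorrelation exp(-gamma * dt); innovations keep the stationary
# per-quadrature variance 1/2.
ou_intensity_chunk <- function(nf, p, a, s, n_modes) {
  acc <- matrix(0, nf, p)
  for (k in seq_len(n_modes)) {
    for (quadrature in 1:2) {
      innov <- matrix(rnorm(nf * p, sd = s), nf, p)
      innov[1L, ] <- rnorm(p, sd = sqrt(0.5))
      e <- stats::filter(innov, a, method = "recursive")
      acc <- acc + e * e
    }
  }
  acc / n_modes
}

#' Pre-detection speckle intensity of diffusing scatterers
#'
#' Generates the normalised (unit-mean) intensity time series of
#' `n_pixels` statistically independent speckle pixels, each the
#' incoherent sum of `n_modes` complex Gaussian field modes evolving by
#' the exact discrete Ornstein-Uhlenbeck step
#' `E(t + dt) = E(t) exp(-gamma dt) + xi sqrt(1 - exp(-2 gamma dt))`
#' with `gamma = D Q^2`. The ensemble intensity autocorrelation is
#' `1 + (1 / n_modes) exp(-2 gamma tau)`.
#'
#' @param n_pixels,n_frames Size of the returned matrix.
#' @param gamma_dt Decay rate per frame, `D Q^2 / frame_rate`
#'   (dimensionless); 0 gives a frozen (static) speckle field.
#' @param n_modes Number of incoherent modes.
#' @return Matrix `n_pixels x n_frames` of unit-mean intensities.
#' @export
speckle_intensity <- function(n_pixels, n_frames, gamma_dt, n_modes = 7L) {
  if (gamma_dt < 0) {
    abort("`gamma_dt` must be >= 0.", class = "saxpcs_invalid_input")
  }
  if (gamma_dt > 50) {
    warn("gamma * dt > 50: dynamics are far faster than the frame rate.")
  }
  a <- exp(-gamma_dt)
  s <- sqrt((1 - a^2) / 2)
  out <- matrix(0, n_pixels, n_frames)
  chunk <- 64L
  for (st in seq(1L, n_pixels, by = chunk)) {
    en <- min(st + chunk - 1L, n_pixels)
    out[st:en, ] <- t(ou_intensity_chunk(n_frames, en - st + 1L, a, s,
                                         n_modes))
  }
  out
}

ring_rates <- function(config) {
  q <- config$ring_spec$q
  rate <- rep(config$mean_count_rate, length(q))
  if (is.numeric(config$form_factor)) {
    p <- polydisperse_intensity(q, config$form_factor[1],
                                config$form_factor[2])
    rate <- config$mean_count_rate * p / p[1]
  }
  rate
}

#' Synthetic Brownian speckle photon events
#'
#' Simulates the photon stream of a dilute Brownian suspension on the
#' rings of `config$ring_spec`: per pixel, `n_modes` independent complex
#' Ornstein-Uhlenbeck field modes with decay rate `gamma = D Q^2`
#' (`D` from the Stokes-Einstein relation applied to the config's
#' radius, temperature and viscosity) give a unit-mean speckle
#' intensity; the emitted count per pixel per frame is a Poisson draw
#' with mean `count rate x intensity`. The normalised autocorrelation of
#' the underlying intensity is `1 + (1/n_modes) exp(-2 D Q^2 tau)`, which
#' is what the downstream correlator and fits assume.
#'
#' @param config A [simulation_config()].
#' @return A [photon_events] tibble; pixels are numbered ring by ring and
#'   `pixel_q(events)` records each pixel's Q.
#' @export
brownian_speckle_sequence <- function(config) {
  simulate_sequence(config, static = FALSE)
}

#' Static (frozen-field) speckle photon events
#'
#' The `gamma = 0` limit of [brownian_speckle_sequence()]: each pixel's
#' speckle intensity is constant in time and only Poisson counting noise
#' fluctuates. Used to calibrate the coherence factor beta as the plateau
#' of `g2 - 1`.
#'
#' @inheritParams brownian_speckle_sequence
#' @return A [photon_events] tibble.
#' @export
static_speckle_sequence <- function(config) {
  simulate_sequence(config, static = TRUE)
}

simulate_sequence <- function(config, static = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nf <- config$n_frames
  d <- diffusivity_from_radius(config$true_r_h_nm, config$temperature_k,
                               config$viscosity_pa_s)
  rates <- ring_rates(config)
  qs <- config$ring_spec$q
  nps <- as.integer(config$ring_spec$n_pixels)
  chunk <- 64L
  parts <- vector("list", length(qs))
  offset <- 0L
  for (r in seq_along(qs)) {
    gamma_dt <- if (static) 0 else d * (qs[r] * 1e9)^2 / config$frame_rate_hz
    if (gamma_dt > 50) {
      warn(sprintf(
        "Ring %d: gamma * dt = %.1f > 50; dynamics much faster than the frame rate.",
        r, gamma_dt))
    }
    a <- exp(-gamma_dt)
    s <- sqrt((1 - a^2) / 2)
    ring_events <- vector("list", ceiling(nps[r] / chunk))
    ci <- 0L
    for (st in seq(1L, nps[r], by = chunk)) {
      en <- min(st + chunk - 1L, nps[r])
      p <- en - st + 1L
      if (static) {
        re <- matrix(rnorm(p * config$n_modes, sd = sqrt(0.5)), p)
        im <- matrix(rnorm(p * config$n_modes, sd = sqrt(0.5)), p)
        ipix <- rowSums(re * re + im * im) / config$n_modes
        # lambda laid out column-major (frame fastest) to match the matrix
        cnt <- matrix(rpois(nf * p, lambda = rep(rates[r] * ipix, each = nf)),
                      nf, p)
      } else {
        intens <- ou_intensity_chunk(nf, p, a, s, config$n_modes)
        cnt <- matrix(rpois(nf * p, lambda = rates[r] * intens), nf, p)
      }
      idx <- which(cnt > 0L)
      ci <- ci + 1L
      ring_events[[ci]] <- tibble(
        frame = (idx - 1L) %% nf,
        pixel = offset + st - 1L + (idx - 1L) %/% nf,
        count = as.integer(cnt[idx])
      )
    }
    parts[[r]] <- dplyr::bind_rows(ring_events)
    offset <- offset + nps[r]
  }
  df <- dplyr::arrange(dplyr::bind_rows(parts), .data$frame, .data$pixel)
  new_photon_events(
    df, nf, sum(nps), config$frame_rate_hz,
    pixel_q = rep(qs, times = nps),
    config = config, seed = config$seed
  )
}

#' Synthetic 1D SAXS curve from the polydisperse sphere model
#'
#' @param r0_nm Mean sphere radius (nm).
#' @param sigma_r_nm Standard deviation of the Gaussian size distribution
#'   (nm).
#' @param q Momentum-transfer grid (nm^-1).
#' @param scale,background Linear scale and constant background.
#' @param noise_sd_rel Relative standard deviation of multiplicative
#'   Gaussian noise (0 = noise-free, fully deterministic).
#' @param seed Seed used only when `noise_sd_rel > 0`.
#' @return A `saxs_curve` tibble (`q`, `intensity`, `sigma`, `n_pixels`).
#' @export
synthetic_saxs_curve <- function(r0_nm, sigma_r_nm, q, scale = 1,
                                 background = 0, noise_sd_rel = 0,
                                 seed = NULL) {
  model <- scale * polydisperse_intensity(q, r0_nm, sigma_r_nm) + background
  intensity <- model
  sigma <- rep(0, length(q))
  if (noise_sd_rel > 0) {
    if (!is.null(seed)) set.seed(seed)
    intensity <- model * (1 + rnorm(length(q), sd = noise_sd_rel))
    sigma <- noise_sd_rel * model
  }
  new_saxs_curve(tibble(q = q, intensity = intensity, sigma = sigma,
                        n_pixels = 1L))
}
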