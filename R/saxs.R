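new_saxs_curve <- function(df) {
  out <- as_tibble(df)
  class(out) <- c("saxs_curve", class(tibble()))
  out
}

#' Time-averaged intensity per pixel
#'
#' Averages a frame sequence over time: per-pixel sum of counts divided
#' by the number of frames, the photon-counting equivalent of a SAXS
#' exposure. Pixels with no events average to 0.
#'
#' @param events A [photon_events] object.
#' @return Tibble with columns `pixel` (0-based) and `intensity` (mean
#'   counts per frame), one row per detector pixel.
#' @export
time_average <- function(events) {
  np <- n_pixels(events)
  nf <- n_frames(events)
  sums <- numeric(np)
  if (nrow(events) > 0) {
    agg <- rowsum(as.numeric(events$count), events$pixel)
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  tibble(pixel = 0:(np - 1L), intensity = sums / nf)
}

#' Azimuthal average of a detector image
#'
#' Averages a per-pixel mean image within the partitions of a Q map
#' (by default the logarithmically spaced SAXS partitions), producing a
#' 1D scattering curve. Per bin the intensity is the mean over unmasked
#' member pixels, the error is the population standard deviation of the
#' member pixels divided by `sqrt(n_pixels)`, and the representative Q is
#' the mean member-pixel Q. Empty partitions are dropped.
#'
#' @param mean_image Tibble (`pixel`, `intensity`) as produced by
#'   [time_average()], or a bare numeric vector ordered by pixel index.
#' @param qmap A `qmap` with partitions.
#' @param partition Which partition scheme to average over.
#' @return A `saxs_curve` tibble (`q`, `intensity`, `sigma`, `n_pixels`),
#'   `q` strictly increasing.
#' @export
azimuthal_average <- function(mean_image, qmap,
                              partition = c("saxs", "fine", "coarse")) {
  partition <- match.arg(partition)
  if (is.numeric(mean_image)) {
    mean_image <- tibble(pixel = seq_along(mean_image) - 1L,
                         intensity = as.numeric(mean_image))
  }
  if (nrow(mean_image) != nrow(qmap)) {
    abort("`mean_image` must have one value per Q-map pixel.",
          class = "saxpcs_invalid_input")
  }
  lab <- qmap[[partition]]
  keep <- qmap$mask & !is.na(lab)
  if (!any(keep)) {
    warn("No unmasked pixels; returning an empty curve.")
    return(new_saxs_curve(tibble(q = numeric(), intensity = numeric(),
                                 sigma = numeric(), n_pixels = integer())))
  }
  df <- tibble(label = lab[keep], q = qmap$q[keep],
               intensity = mean_image$intensity[match(qmap$pixel[keep],
                                                      mean_image$pixel)])
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$label),
    q = mean(.data$q),
    sigma = pop_sd(.data$intensity) / sqrt(dplyr::n()),
    intensity = mean(.data$intensity),
    n_pixels = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$q)
  new_saxs_curve(out[, c("q", "intensity", "sigma", "n_pixels")])
}

# population (n-denominator) standard deviation
pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Scattering amplitude of a uniform sphere
#'
#' `A(x) = 3 (sin x - x cos x) / x^3` with `A(0) = 1`; for `x < 1e-3` the
#' series `1 - x^2 / 10` is used for numerical stability.
#'
#' @param x Dimensionless `q R`.
#' @return Amplitude in `[-...,1]`; the first zero sits at
#'   `x = 4.4934...`.
#' @export
sphere_amplitude <- function(x) {
  if (any(x < 0)) {
    abort("`x` must be >= 0.", class = "saxpcs_invalid_input")
  }
  out <- numeric(length(x))
  small <- x < 1e-3
  out[small] <- 1 - x[small]^2 / 10
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Normalised intensity of Gaussian-polydisperse spheres
#'
#' Number-weighted Gaussian distribution of radii with intensity
#' weighting `V(R)^2`, the standard parameterisation for nearly
#' monodisperse nanospheres:
#' `P(q) = int N(R; R0, sigma) V(R)^2 A(qR)^2 dR / int N V^2 dR`,
#' evaluated by quadrature on a fixed grid of 129 points covering
#' `R0 +/- 4 sigma` (truncated at `R > 0`), so `P(0) = 1`. With
#' `sigma_r_nm = 0` it reduces to the monodisperse `A(q R0)^2`.
#'
#' @param q Momentum transfer (nm^-1), vectorised.
#' @param r0_nm Mean radius (nm).
#' @param sigma_r_nm Standard deviation of the radius (nm).
#' @param n_grid Number of quadrature points.
#' @return `P(q)`, dimensionless, `P(0) = 1`.
#' @export
polydisperse_intensity <- function(q, r0_nm, sigma_r_nm, n_grid = 129L) {
  if (r0_nm <= 0 || sigma_r_nm < 0) {
    abort("`r0_nm` must be > 0 and `sigma_r_nm` >= 0.",
          class = "saxpcs_invalid_input")
  }
  if (sigma_r_nm == 0) {
    return(sphere_amplitude(q * r0_nm)^2)
  }
  if (sigma_r_nm > r0_nm / 2) {
    warn("sigma_r > R0/2: the +/- 4 sigma quadrature truncates noticeably.")
  }
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L   # Simpson needs odd
  r <- seq(max(r0_nm - 4 * sigma_r_nm, .Machine$double.eps),
           r0_nm + 4 * sigma_r_nm, length.out = n_grid)
  simpson <- c(1, rep(c(4, 2), length.out = n_grid - 2L), 1)
  w <- simpson * dnorm(r, r0_nm, sigma_r_nm) * r^6    # V(R)^2 ~ R^6
  amp2 <- outer(q, r, function(qi, ri) sphere_amplitude(qi * ri)^2)
  as.numeric(amp2 %*% w) / sum(w)
}

#' Fit the polydisperse sphere form factor to a 1D SAXS curve
#'
#' Weighted least squares on log-intensity residuals (SAXS spans decades,
#' so log residuals weight all features fairly) of the model
#' `I(q) = scale * P(q; R0, sigma_R) + background`. Weights come from the
#' propagated relative errors `sigma / intensity`; bins with zero or
#' missing error get the median positive relative error (or unit weight
#' for a noise-free curve).
#'
#' @param curve A `saxs_curve` (columns `q`, `intensity`, `sigma`).
#' @param init Named or positional numeric `(r0, sigma_r, scale,
#'   background)` starting values; `scale = NA` starts at the value
#'   matching the first bin.
#' @param q_range Optional length-2 Q window (nm^-1) to fit.
#' @return A `form_factor_fit` object; see [tidy()] / [glance()] for the
#'   estimates `r0`, `sigma_r`, `scale`, `background` with standard
#'   errors, covariance and reduced chi-square.
#' @export
fit_form_factor <- function(curve, init = c(10, 2, NA, 0), q_range = NULL) {
  df <- as_tibble(curve)[, c("q", "intensity", "sigma")]
  if (!is.null(q_range)) {
    df <- df[df$q >= q_range[1] & df$q <= q_range[2], ]
  }
  df <- df[is.finite(df$intensity) & df$intensity > 0, ]
  if (nrow(df) < 8L) {
    abort("Need at least 8 positive-intensity bins in the fit range.",
          class = "saxpcs_fit_error")
  }
  init <- as.numeric(init)
  if (is.na(init[3])) {
    init[3] <- df$intensity[1] /
      max(polydisperse_intensity(df$q[1], init[1], init[2]), 1e-12)
  }
  rel <- df$sigma / df$intensity
  rel[!is.finite(rel) | rel <= 0] <- NA
  fill <- median(rel, na.rm = TRUE)
  if (!is.finite(fill)) fill <- 1
  rel[is.na(rel)] <- fill
  w <- 1 / rel^2

  logi <- log(df$intensity)
  sw <- sqrt(w)
  model_log <- function(p) {
    log(pmax(p[3] * polydisperse_intensity(df$q, p[1], p[2]) + p[4], 1e-300))
  }
  fit <- minpack.lm::nls.lm(
    par = init,
    fn = function(p) sw * (model_log(p) - logi),
    lower = c(1e-3, 0, 1e-300, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!(fit$info %in% 1:4) || any(!is.finite(fit$par))) {
    abort(paste0("Form-factor fit failed to converge: ", fit$message),
          class = "saxpcs_fit_error", last_iterate = fit$par)
  }
  est <- setNames(fit$par, c("r0", "sigma_r", "scale", "background"))
  dof <- max(nrow(df) - 4L, 1L)
  s2 <- fit$deviance / dof
  covar <- tryCatch(solve(fit$hessian) * s2,
                    error = function(e) matrix(NA_real_, 4, 4))
  dimnames(covar) <- list(names(est), names(est))
  resid <- logi - model_log(fit$par)   # observed - fitted, log scale
  structure(
    list(
      r0 = est[["r0"]], sigma_r = est[["sigma_r"]],
      scale = est[["scale"]], background = est[["background"]],
      se = sqrt(pmax(diag(covar), 0)),
      covariance = covar,
      chisq_reduced = sum(w * resid^2) / dof,
      q_range = range(df$q),
      n_bins = nrow(df),
      curve = df,
      fitted_intensity = exp(model_log(fit$par)),
      residuals_log = resid
    ),
    class = "form_factor_fit"
  )
}

#' @export
print.form_factor_fit <- function(x, ...) {
  cat("<form_factor_fit>  Gaussian-polydisperse sphere\n")
  cat(sprintf("  R0      = %.3f +/- %.3f nm\n", x$r0, x$se["r0"]))
  cat(sprintf("  sigma_R = %.3f +/- %.3f nm\n", x$sigma_r, x$se["sigma_r"]))
  cat(sprintf("  scale = %.4g, background = %.4g\n", x$scale, x$background))
  cat(sprintf("  reduced chi-square = %.4g over %d bins, q in [%.4g, %.4g] nm^-1\n",
              x$chisq_reduced, x$n_bins, x$q_range[1], x$q_range[2]))
  invisible(x)
}

#' @export
tidy.form_factor_fit <- function(x, ...) {
  tibble(
    term = c("r0", "sigma_r", "scale", "background"),
    estimate = c(x$r0, x$sigma_r, x$scale, x$background),
    std.error = as.numeric(x$se[c("r0", "sigma_r", "scale", "background")])
  )
}

#' @export
glance.form_factor_fit <- function(x, ...) {
  tibble(
    r0 = x$r0, sigma_r = x$sigma_r,
    chisq_reduced = x$chisq_reduced,
    n_bins = x$n_bins,
    q_min = x$q_range[1], q_max = x$q_range[2]
  )
}

#' @export
augment.form_factor_fit <- function(x, ...) {
  tibble(
    q = x$curve$q,
    intensity = x$curve$intensity,
    sigma = x$curve$sigma,
    fitted = x$fitted_intensity,
    residual_log = x$residuals_log
  )
}
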