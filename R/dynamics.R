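#' Sample environment for Stokes-Einstein inference
#'
#' @param temperature_k Temperature in K.
#' @param viscosity_pa_s Dynamic viscosity in Pa s (e.g. water at 6 C is
#'   1.520e-3; added electrolytes raise it).
#' @param label Free-text sample label.
#' @return An `environment_spec` list; the Boltzmann constant is fixed at
#'   1.380649e-23 J/K.
#' @export
environment_spec <- function(temperature_k = 279,
                             viscosity_pa_s = 1.520e-3,
                             label = "") {
  check_positive_scalar(temperature_k, "temperature_k")
  check_positive_scalar(viscosity_pa_s, "viscosity_pa_s")
  structure(
    list(temperature_k = temperature_k, viscosity_pa_s = viscosity_pa_s,
         boltzmann = k_boltzmann, label = label),
    class = "environment_spec"
  )
}

#' Fit a single-exponential decay to one g2(tau) curve
#'
#' Weighted nonlinear least squares of
#' `g2(tau) - 1 = beta * exp(-2 tau / tau0)`. By default the coherence
#' factor `beta` is held fixed at the static-reference value and only the
#' decay time `tau0` is fitted; `beta_free = TRUE` also fits `beta`
#' (diagnostic mode). Zero or missing errors are replaced by the median
#' positive error so every point keeps finite weight.
#'
#' @param delays Delay times (s).
#' @param g2 Normalised autocorrelation values.
#' @param sigma_g2 Errors on `g2` (any common scale; weights are
#'   relative).
#' @param beta Coherence factor (fixed value, or starting value when
#'   free).
#' @param beta_free Fit `beta` as well?
#' @param tau_bounds Allowed `tau0` range (s); estimates at a bound are
#'   flagged unconverged.
#' @return One-row tibble: `tau0`, `sigma_tau0`, `beta`, `sigma_beta`,
#'   `chisq_reduced`, `n_points`, `converged`. Degenerate input yields
#'   `converged = FALSE` with `NA` estimates rather than an error.
#' @export
fit_single_exponential <- function(delays, g2, sigma_g2 = NULL,
                                   beta = 1 / 7, beta_free = FALSE,
                                   tau_bounds = c(1e-7, 1e3)) {
  ok <- is.finite(delays) & is.finite(g2)
  delays <- delays[ok]
  dg <- g2[ok] - 1
  sig <- if (is.null(sigma_g2)) rep(NA_real_, sum(ok)) else sigma_g2[ok]
  failed <- tibble(tau0 = NA_real_, sigma_tau0 = NA_real_,
                   beta = NA_real_, sigma_beta = NA_real_,
                   chisq_reduced = NA_real_, n_points = length(dg),
                   converged = FALSE)
  if (length(dg) < 6L) return(failed)
  sig[!is.finite(sig) | sig <= 0] <- NA
  fill <- median(sig, na.rm = TRUE)
  if (!is.finite(fill)) fill <- 1
  sig[is.na(sig)] <- fill
  w <- 1 / sig^2

  # initial tau0 from the log-linear early decay, falling back to the
  # delay nearest the 1/e point
  pos <- dg > 0.05 * beta
  tau0_init <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(dg[pos]) ~ delays[pos],
                                weights = w[pos]))[2]
    if (is.finite(sl) && sl < 0) -2 / sl else NA_real_
  } else NA_real_
  if (!is.finite(tau0_init) || tau0_init <= 0) {
    near <- which.min(abs(dg - beta / exp(1)))
    tau0_init <- max(delays[near], min(delays[delays > 0]))
  }
  tau0_init <- min(max(tau0_init, tau_bounds[1] * 2), tau_bounds[2] / 2)

  dat <- list(tau = delays, dg = dg)
  fit <- tryCatch({
    if (beta_free) {
      minpack.lm::nlsLM(dg ~ b * exp(-2 * tau / tau0), data = dat,
                        start = list(tau0 = tau0_init, b = max(beta, 1e-3)),
                        weights = w,
                        lower = c(tau0 = tau_bounds[1], b = 1e-6),
                        upper = c(tau0 = tau_bounds[2], b = 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(dg ~ beta * exp(-2 * tau / tau0), data = dat,
                        start = list(tau0 = tau0_init), weights = w,
                        lower = c(tau0 = tau_bounds[1]),
                        upper = c(tau0 = tau_bounds[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed)

  cf <- summary(fit)$coefficients
  tau0 <- cf["tau0", "Estimate"]
  # a decay faster than half the smallest sampled delay is unresolvable
  # (the model predicts ~0 everywhere, as for dg2 identically 0)
  at_bound <- tau0 <= tau_bounds[1] * (1 + 1e-6) ||
    tau0 >= tau_bounds[2] * (1 - 1e-6) ||
    tau0 < 0.5 * min(delays[delays > 0])
  resid <- stats::residuals(fit)
  dof <- max(length(dg) - nrow(cf), 1L)
  tibble(
    tau0 = tau0,
    sigma_tau0 = cf["tau0", "Std. Error"],
    beta = if (beta_free) cf["b", "Estimate"] else beta,
    sigma_beta = if (beta_free) cf["b", "Std. Error"] else 0,
    chisq_reduced = sum(w * resid^2) / dof,
    n_points = length(dg),
    converged = !at_bound
  )
}

#' Exponential fits of g2 for every coarse Q partition
#'
#' Applies [fit_single_exponential()] to each coarse-Q curve of a
#' `g2_result`.
#'
#' @param g2res A `g2_result` from [normalize_g2()].
#' @param beta,beta_free,tau_bounds Passed to
#'   [fit_single_exponential()].
#' @param min_points Minimum usable delay points per Q.
#' @return A `g2_fit` tibble, one row per coarse Q: `q`, `tau0`,
#'   `sigma_tau0`, `beta`, `sigma_beta`, `chisq_reduced`, `n_points`,
#'   `converged`.
#' @export
fit_g2 <- function(g2res, beta = 1 / 7, beta_free = FALSE,
                   tau_bounds = c(1e-7, 1e3), min_points = 6L) {
  fits <- g2res |>
    dplyr::group_by(.data$coarse, .data$q) |>
    dplyr::group_modify(function(d, key) {
      d <- d[is.finite(d$g2), ]
      if (nrow(d) < min_points) {
        return(tibble(tau0 = NA_real_, sigma_tau0 = NA_real_,
                      beta = NA_real_, sigma_beta = NA_real_,
                      chisq_reduced = NA_real_, n_points = nrow(d),
                      converged = FALSE))
      }
      fit_single_exponential(d$delay_s, d$g2, d$sigma_g2, beta = beta,
                             beta_free = beta_free, tau_bounds = tau_bounds)
    }) |>
    dplyr::ungroup()
  class(fits) <- c("g2_fit", class(tibble()))
  attr(fits, "g2_result") <- g2res
  attr(fits, "beta_mode") <- if (beta_free) "free" else "fixed"
  fits
}

#' @export
tidy.g2_fit <- function(x, ...) as_tibble(x)

#' @export
glance.g2_fit <- function(x, ...) {
  tibble(n_q = nrow(x), n_converged = sum(x$converged),
         beta_mode = attr(x, "beta_mode") %||% NA_character_)
}

#' Diffusivity from the Q dependence of the decay time
#'
#' Brownian motion predicts `tau0(Q) = 1 / (D Q^2)`. The decay rates
#' `Gamma = 1 / tau0` of all converged fits with `Q <= q_max` are
#' regressed on `Q^2` through the origin by weighted linear least squares
#' (weights `1 / sigma_Gamma^2`, with `sigma_Gamma = sigma_tau0 / tau0^2`
#' propagated from the exponential fits); the slope is `D` in SI units.
#'
#' @param g2fits A `g2_fit` table.
#' @param q_max Largest Q (nm^-1) entering the fit; beyond ~0.1 nm^-1
#'   the single-exponential description degrades for virus-scale
#'   particles.
#' @return A `diffusion_fit` object with `d` (m^2/s), `sigma_d`, per-Q
#'   residuals, `chisq_reduced` and the fitted subset; the hydrodynamic
#'   radius is attached by [stokes_einstein_radius()].
#' @export
fit_tau_vs_q <- function(g2fits, q_max = 0.1) {
  sub <- g2fits[g2fits$converged & is.finite(g2fits$tau0) &
                  g2fits$q <= q_max, ]
  if (nrow(sub) < 3L) {
    abort(sprintf(
      "Only %d converged Q point(s) at or below q_max = %g nm^-1; need >= 3.",
      nrow(sub), q_max), class = "saxpcs_insufficient_data")
  }
  gamma <- 1 / sub$tau0
  sigma_gamma <- sub$sigma_tau0 / sub$tau0^2
  w <- 1 / sigma_gamma^2
  if (any(!is.finite(w) | w <= 0)) w <- rep(1, nrow(sub))
  x <- (sub$q * 1e9)^2                     # nm^-1 -> m^-1, squared
  d <- sum(w * gamma * x) / sum(w * x^2)
  sigma_d <- sqrt(1 / sum(w * x^2))
  resid <- gamma - d * x
  chisq <- sum(w * resid^2) / max(nrow(sub) - 1L, 1L)
  structure(
    list(
      d = d, sigma_d = sigma_d,
      q_max_used = q_max,
      data = dplyr::mutate(sub, gamma = gamma, sigma_gamma = sigma_gamma,
                           gamma_fit = d * x, residual = resid),
      chisq_reduced = chisq,
      r_h_nm = NA_real_, sigma_r_h_nm = NA_real_, env = NULL
    ),
    class = "diffusion_fit"
  )
}

#' Hydrodynamic radius via the Stokes-Einstein relation
#'
#' `R_H = kT / (6 pi eta D)`; the relative error of `D` propagates
#' unchanged, `sigma_R_H / R_H = sigma_D / D`.
#'
#' @param fit A `diffusion_fit` from [fit_tau_vs_q()].
#' @param env An [environment_spec()] with the sample temperature and
#'   viscosity.
#' @return The `diffusion_fit` with `r_h_nm`, `sigma_r_h_nm` and `env`
#'   filled in.
#' @export
stokes_einstein_radius <- function(fit, env) {
  stopifnot(inherits(fit, "diffusion_fit"), inherits(env, "environment_spec"))
  if (!is.finite(fit$d) || fit$d <= 0) {
    abort("Diffusivity must be positive to invert Stokes-Einstein.",
          class = "saxpcs_invalid_input")
  }
  fit$r_h_nm <- radius_from_diffusivity(fit$d, env$temperature_k,
                                        env$viscosity_pa_s)
  fit$sigma_r_h_nm <- fit$r_h_nm * fit$sigma_d / fit$d
  fit$env <- env
  fit
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit>  Gamma = D Q^2 through the origin\n")
  cat(sprintf("  D   = %.4g +/- %.2g m^2/s  (%d Q points, q_max %.3g nm^-1, red. chi^2 %.3g)\n",
              x$d, x$sigma_d, nrow(x$data), x$q_max_used, x$chisq_reduced))
  if (is.finite(x$r_h_nm)) {
    cat(sprintf("  R_H = %.2f +/- %.2f nm  (T = %g K, eta = %.4g Pa s%s)\n",
                x$r_h_nm, x$sigma_r_h_nm, x$env$temperature_k,
                x$env$viscosity_pa_s,
                if (nzchar(x$env$label)) paste0(", ", x$env$label) else ""))
  }
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  as_tibble(x$data)
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(
    d = x$d, sigma_d = x$sigma_d,
    r_h_nm = x$r_h_nm, sigma_r_h_nm = x$sigma_r_h_nm,
    q_max_used = x$q_max_used,
    n_q = nrow(x$data),
    chisq_reduced = x$chisq_reduced,
    temperature_k = if (is.null(x$env)) NA_real_ else x$env$temperature_k,
    viscosity_pa_s = if (is.null(x$env)) NA_real_ else x$env$viscosity_pa_s
  )
}
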