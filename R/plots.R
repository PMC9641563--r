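#' Plot a 1D SAXS curve
#'
#' @param object A `saxs_curve`.
#' @param ... Unused.
#' @return A ggplot (log-log intensity vs Q with error bars).
#' @export
autoplot.saxs_curve <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$intensity > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$intensity - .data$sigma,
                                        ymax = .data$intensity + .data$sigma),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (nm^-1)),
                  y = "intensity (counts / pixel / frame)")
}

#' Plot a form-factor fit over its data
#'
#' @param object A `form_factor_fit`.
#' @param ... Unused.
#' @return A ggplot: measured curve, fitted polydisperse-sphere model and
#'   log residuals.
#' @export
autoplot.form_factor_fit <- function(object, ...) {
  df <- augment(object)
  df <- df[df$intensity > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(Q ~ (nm^-1)), y = "intensity",
      subtitle = sprintf("R0 = %.2f +/- %.2f nm, sigma_R = %.2f nm",
                         object$r0, object$se["r0"], object$sigma_r))
}

#' Plot g2 - 1 against delay per Q partition
#'
#' @param object A `g2_result`.
#' @param ... Unused.
#' @return A ggplot of `g2 - 1` vs delay (log x), one colour per Q.
#' @export
autoplot.g2_result <- function(object, ...) {
  df <- as_tibble(object)
  df$q_label <- sprintf("Q = %.3g", df$q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_s, y = .data$g2 - 1,
                                   colour = .data$q_label)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$g2 - 1 - .data$sigma_g2,
                                        ymax = .data$g2 - 1 + .data$sigma_g2),
                           width = 0, alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ (s)), y = expression(g[2] - 1),
                  colour = expression(Q ~ (nm^-1)))
}

#' Plot per-Q exponential fits over the g2 data
#'
#' @param object A `g2_fit` (from [fit_g2()]).
#' @param ... Unused.
#' @return A ggplot with the fitted `beta exp(-2 tau / tau0)` curves
#'   overlaid on `g2 - 1`.
#' @export
autoplot.g2_fit <- function(object, ...) {
  g2res <- attr(object, "g2_result")
  p <- autoplot(g2res)
  fits <- as_tibble(object)
  fits <- fits[fits$converged, ]
  if (nrow(fits) > 0) {
    curves <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
      tau <- exp(seq(log(min(g2res$delay_s)), log(max(g2res$delay_s)),
                     length.out = 100))
      tibble(delay_s = tau,
             dg2 = fits$beta[i] * exp(-2 * tau / fits$tau0[i]),
             q_label = sprintf("Q = %.3g", fits$q[i]))
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$delay_s, y = .data$dg2,
                   colour = .data$q_label),
      inherit.aes = FALSE)
  }
  p
}

#' Plot the decay time against Q with the Brownian prediction
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot of `tau0(Q)` (log-log) with the fitted
#'   `1 / (D Q^2)` line.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  df <- object$data
  line <- tibble(q = seq(min(df$q), max(df$q), length.out = 100))
  line$tau0 <- 1 / (object$d * (line$q * 1e9)^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$tau0)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$tau0 - .data$sigma_tau0,
                                        ymax = .data$tau0 + .data$sigma_tau0),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red", linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (nm^-1)),
                  y = expression(tau[0] ~ (s)),
                  subtitle = sprintf("D = %.3g m^2/s%s", object$d,
                                     if (is.finite(object$r_h_nm))
                                       sprintf(", R_H = %.2f nm",
                                               object$r_h_nm) else ""))
}
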