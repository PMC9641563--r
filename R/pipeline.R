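#' Configuration for a full simulate-reduce-correlate-fit run
#'
#' @param simulation A [simulation_config()] (ground truth and acquisition
#'   settings for the synthetic stage), or `NULL` when events are supplied
#'   directly to [run_pipeline()].
#' @param correlator List: `channels_per_level`, `max_lag_frac`, `error`
#'   (g2 error bar type), `flag_pixels` (run the bad-pixel flagger?).
#' @param fit List: `beta` (coherence factor; default `1 / n_modes` of the
#'   simulation), `beta_free`, `q_max` (nm^-1).
#' @param environment An [environment_spec()]; defaults to the
#'   simulation's temperature and viscosity.
#' @param saxs List: `fit` (fit the sphere form factor to the reduced
#'   curve?), `init`, `q_range`.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       correlator = list(),
                       fit = list(),
                       environment = NULL,
                       saxs = list()) {
  correlator <- modifyList(
    list(channels_per_level = 8L, max_lag_frac = 1 / 4,
         error = "population", flag_pixels = TRUE),
    correlator)
  default_beta <- if (is.null(simulation)) 1 / 7 else 1 / simulation$n_modes
  fit <- modifyList(
    list(beta = default_beta, beta_free = FALSE, q_max = 0.1), fit)
  saxs <- modifyList(
    list(fit = FALSE, init = c(10, 2, NA, 0), q_range = NULL), saxs)
  if (is.null(environment)) {
    environment <- if (is.null(simulation)) environment_spec()
      else environment_spec(simulation$temperature_k,
                            simulation$viscosity_pa_s)
  }
  structure(
    list(simulation = simulation, correlator = correlator, fit = fit,
         environment = environment, saxs = saxs),
    class = "run_config"
  )
}

run_stage <- function(run, stage, fun) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(fun(), error = function(e) {
    run$complete <- FALSE
    abort(
      sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "saxpcs_stage_error", stage = stage, partial = run,
      parent = e)
  })
  run$stages <- dplyr::bind_rows(
    run$stages,
    tibble(stage = stage, ok = TRUE, hash = rlang::hash(value),
           seconds = proc.time()[["elapsed"]] - t0))
  run$value <- value
  run
}

#' Run the full XPCS analysis pipeline
#'
#' Executes simulate (unless `events` are supplied), SAXS reduction,
#' multi-tau correlation, bad-pixel flagging, normalisation, per-Q
#' exponential fits, the `Gamma = D Q^2` fit and the Stokes-Einstein
#' inversion, recording one structured record (hash, wall time) per
#' stage. Reruns with the same config are identical: all randomness flows
#' from the simulation seed.
#'
#' @param config A [run_config()].
#' @param events Optional [photon_events]; skips the simulation stage.
#' @param qmap Optional `qmap`; by default a ring map is built from the
#'   events' per-pixel Q table.
#' @return An `xpcs_run` list: `events`, `qmap`, `saxs` (curve),
#'   `form_fit` (optional), `acc`, `flags`, `g2`, `g2fit`, `dfit` (with
#'   `r_h_nm`), `stages`, `config`. On stage failure an error of class
#'   `saxpcs_stage_error` is raised carrying the stage name and the
#'   partial results (`complete = FALSE`).
#' @export
run_pipeline <- function(config, events = NULL, qmap = NULL) {
  stopifnot(inherits(config, "run_config"))
  run <- list(config = config, stages = tibble(), complete = FALSE)

  if (is.null(events)) {
    if (is.null(config$simulation)) {
      abort("Either `events` or a simulation config is required.",
            class = "saxpcs_invalid_input")
    }
    run <- run_stage(run, "simulate",
                     function() brownian_speckle_sequence(config$simulation))
    events <- run$value
  }
  run$events <- events

  if (is.null(qmap)) {
    run <- run_stage(run, "qmap", function() {
      pq <- pixel_q(events)
      if (is.null(pq)) {
        abort("No `qmap` given and the events carry no per-pixel Q table.")
      }
      rq <- unique(pq)
      ring_qmap(rq, as.integer(table(factor(pq, levels = rq))),
                frame_rate(events))
    })
    qmap <- run$value
  }
  run$qmap <- qmap

  run <- run_stage(run, "reduce_saxs", function() {
    azimuthal_average(time_average(events), qmap, partition = "saxs")
  })
  run$saxs <- run$value

  if (isTRUE(config$saxs$fit)) {
    run <- run_stage(run, "fit_form_factor", function() {
      fit_form_factor(run$saxs, init = config$saxs$init,
                      q_range = config$saxs$q_range)
    })
    run$form_fit <- run$value
  }

  run <- run_stage(run, "correlate", function() {
    lags <- multitau_lags(n_frames(events), frame_rate(events),
                          config$correlator$channels_per_level,
                          config$correlator$max_lag_frac)
    correlate_multitau(events, qmap, lags)
  })
  run$acc <- run$value

  run <- run_stage(run, "flag_pixels", function() {
    if (isTRUE(config$correlator$flag_pixels)) flag_bad_pixels(run$acc)
    else rep(FALSE, nrow(run$acc$pixels))
  })
  run$flags <- run$value

  run <- run_stage(run, "normalize", function() {
    normalize_g2(run$acc, flags = run$flags,
                 error = config$correlator$error, beta = config$fit$beta)
  })
  run$g2 <- run$value

  run <- run_stage(run, "fit_g2", function() {
    fit_g2(run$g2, beta = config$fit$beta,
           beta_free = config$fit$beta_free)
  })
  run$g2fit <- run$value

  run <- run_stage(run, "fit_diffusivity", function() {
    fit_tau_vs_q(run$g2fit, q_max = config$fit$q_max)
  })
  run <- run_stage(run, "stokes_einstein", function() {
    stokes_einstein_radius(run$value, config$environment)
  })
  run$dfit <- run$value

  run$value <- NULL
  run$complete <- TRUE
  class(run) <- "xpcs_run"
  run
}

#' @export
print.xpcs_run <- function(x, ...) {
  cat("<xpcs_run>", if (x$complete) "complete" else "INCOMPLETE", "\n")
  print(x$stages)
  if (!is.null(x$dfit)) print(x$dfit)
  invisible(x)
}

#' @export
glance.xpcs_run <- function(x, ...) {
  if (is.null(x$dfit)) return(tibble())
  glance(x$dfit)
}

#' Split a frame sequence into contiguous subsets
#'
#' Cuts the acquisition into `n_subsets` equal contiguous blocks of
#' frames (trailing remainder frames are dropped), each re-based to start
#' at frame 0. Used for the radiation-damage / stability diagnostic.
#'
#' @param events A [photon_events] object.
#' @param n_subsets Number of blocks.
#' @return List of [photon_events].
#' @export
split_events <- function(events, n_subsets = 2L) {
  nf <- n_frames(events) %/% n_subsets
  if (nf < 1L) {
    abort("More subsets than frames.", class = "saxpcs_invalid_input")
  }
  lapply(seq_len(n_subsets), function(i) {
    lo <- (i - 1L) * nf
    sel <- events$frame >= lo & events$frame < lo + nf
    df <- tibble(frame = events$frame[sel] - lo,
                 pixel = events$pixel[sel],
                 count = events$count[sel])
    new_photon_events(df, nf, n_pixels(events), frame_rate(events),
                      pixel_q = pixel_q(events))
  })
}

pair_chisq <- function(a, b, sa, sb) {
  den <- sa^2 + sb^2
  d2 <- (a - b)^2
  term <- ifelse(d2 == 0, 0, d2 / den)
  keep <- is.finite(term)
  if (!any(keep)) return(NA_real_)
  mean(term[keep])
}

#' Consistency check among measurement subsets
#'
#' Compares SAXS curves and g2 curves from subsets of one acquisition
#' (e.g. halves, or consecutive repeats) by pairwise reduced chi-square
#' with combined errors. Mutually consistent subsets indicate a
#' stationary sample -- in particular, no radiation damage over the
#' acquisition. All pairs (and for g2, every Q) must fall below
#' `threshold` to pass.
#'
#' @param subsets List where each element has components `saxs` (a
#'   `saxs_curve`) and/or `g2` (a `g2_result` with per-point errors; use
#'   `error = "sem"` in [normalize_g2()] so the chi-square is on the
#'   mean).
#' @param threshold Reduced chi-square pass threshold.
#' @return A `stability_report`: tibbles `saxs` (`i`, `j`,
#'   `chisq_reduced`), `g2` (per-Q diagnostics) and `g2_pairs` (one
#'   pooled statistic per pair, used for the verdict), plus `pass` and
#'   `threshold`.
#' @export
check_stability <- function(subsets, threshold = 2) {
  if (length(subsets) < 2L) {
    abort("Need at least 2 subsets.", class = "saxpcs_invalid_input")
  }
  subsets <- lapply(subsets, function(s) {
    if (inherits(s, "xpcs_run")) list(saxs = s$saxs, g2 = s$g2) else s
  })
  pairs <- utils::combn(length(subsets), 2L)
  saxs_tab <- NULL
  g2_tab <- NULL
  g2_pair <- NULL
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    si <- subsets[[i]]$saxs; sj <- subsets[[j]]$saxs
    if (!is.null(si) && !is.null(sj)) {
      if (nrow(si) != nrow(sj) || max(abs(si$q - sj$q)) > 1e-9) {
        abort("Subset SAXS curves have mismatched Q binning.",
              class = "saxpcs_structure_error")
      }
      saxs_tab <- dplyr::bind_rows(saxs_tab, tibble(
        i = i, j = j,
        chisq_reduced = pair_chisq(si$intensity, sj$intensity,
                                   si$sigma, sj$sigma)))
    }
    gi <- subsets[[i]]$g2; gj <- subsets[[j]]$g2
    if (!is.null(gi) && !is.null(gj)) {
      if (nrow(gi) != nrow(gj) ||
          !isTRUE(all.equal(gi$lag_frames, gj$lag_frames)) ||
          !isTRUE(all.equal(gi$coarse, gj$coarse))) {
        abort("Subset g2 results have mismatched binning.",
              class = "saxpcs_structure_error")
      }
      for (cc in unique(gi$coarse)) {
        a <- gi[gi$coarse == cc, ]; b <- gj[gj$coarse == cc, ]
        g2_tab <- dplyr::bind_rows(g2_tab, tibble(
          i = i, j = j, q = a$q[1],
          chisq_reduced = pair_chisq(a$g2, b$g2, a$sigma_g2, b$sigma_g2)))
      }
      g2_pair <- dplyr::bind_rows(g2_pair, tibble(
        i = i, j = j,
        chisq_reduced = pair_chisq(gi$g2, gj$g2, gi$sigma_g2,
                                   gj$sigma_g2)))
    }
  }
  # the pass verdict uses one statistic per pair (g2 pooled over Q and
  # delay) so its null distribution has enough effective degrees of
  # freedom; the per-Q table is kept for diagnostics
  all_chisq <- c(saxs_tab$chisq_reduced, g2_pair$chisq_reduced)
  structure(
    list(saxs = saxs_tab, g2 = g2_tab, g2_pairs = g2_pair,
         pass = all(all_chisq < threshold, na.rm = TRUE),
         threshold = threshold),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", if (x$pass) "PASS" else "FAIL",
      sprintf("(threshold %.3g)\n", x$threshold))
  if (!is.null(x$saxs)) {
    cat(sprintf("  SAXS pairs: max reduced chi^2 = %.3g\n",
                max(x$saxs$chisq_reduced, na.rm = TRUE)))
  }
  if (!is.null(x$g2)) {
    cat(sprintf("  g2 pairs  : max reduced chi^2 = %.3g\n",
                max(x$g2$chisq_reduced, na.rm = TRUE)))
  }
  invisible(x)
}
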