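#' Multi-tau delay structure
#'
#' Builds the exponentially recursive lag ladder of a multi-tau
#' correlator: level 0 holds lags `1..channels_per_level` at native frame
#' resolution; every higher level doubles the frame-binning width and
#' holds channels `(c/2, c]` at spacing `2^level` frames, so delay
#' coverage grows geometrically at fixed cost. Lags beyond
#' `max_lag_frac * n_frames` are dropped as statistically unreliable.
#'
#' @param n_frames Frames in the sequence.
#' @param frame_rate_hz Frame rate (Hz); the smallest delay is
#'   `1 / frame_rate_hz`.
#' @param channels_per_level Channels per level (even, >= 2).
#' @param max_lag_frac Largest usable lag as a fraction of `n_frames`.
#' @param max_level Optional cap on the number of doubling levels.
#' @return A `multitau_lags` tibble (`level`, `channel`, `lag_frames`,
#'   `lag_s`), strictly increasing in lag.
#' @export
multitau_lags <- function(n_frames, frame_rate_hz = 52000,
                          channels_per_level = 8L, max_lag_frac = 1 / 4,
                          max_level = Inf) {
  c <- as.integer(channels_per_level)
  if (c < 2L || c %% 2L != 0L) {
    abort("`channels_per_level` must be an even integer >= 2.",
          class = "saxpcs_invalid_input")
  }
  if (n_frames <= c) {
    abort("`n_frames` must exceed `channels_per_level`.",
          class = "saxpcs_invalid_input")
  }
  max_lag <- floor(n_frames * max_lag_frac)
  rows <- list(tibble(level = 0L, channel = 1:c, lag_frames = 1:c))
  lev <- 1L
  while (lev <= max_level) {
    lf <- ((c %/% 2L + 1L):c) * 2L^lev
    if (lf[1] > max_lag) break
    rows[[lev + 1L]] <- tibble(level = lev, channel = (c %/% 2L + 1L):c,
                               lag_frames = lf)
    lev <- lev + 1L
  }
  out <- dplyr::bind_rows(rows)
  out <- out[out$lag_frames <= max_lag, ]
  out$lag_s <- out$lag_frames / frame_rate_hz
  structure(out, class = c("multitau_lags", class(tibble())))
}

halve_frames <- function(m) {
  t2 <- ncol(m) %/% 2L
  if (t2 == 0L) return(NULL)
  (m[, seq(1L, 2L * t2, by = 2L), drop = FALSE] +
     m[, seq(2L, 2L * t2, by = 2L), drop = FALSE]) / 2
}

#' Multi-tau correlation sums of a sparse photon stream
#'
#' Computes, per pixel and per delay, the unnormalised correlator sums
#' `G2(tau) = <I(t) I(t + tau)>_t`, `IF(tau) = <I(t)>` over
#' `t in [0, T - tau]` and `IP(tau) = <I(t + tau)>` over
#' `t + tau in [tau, T]` (symmetric normalisation windows). At level `l`
#' of the multi-tau ladder, frames are pre-averaged in non-overlapping
#' blocks of `2^l` (intensity-preserving block means) before products are
#' formed, so a constant stream satisfies `G2 = IF * IP` exactly at every
#' level.
#'
#' @param events A [photon_events] object.
#' @param qmap A `qmap` with fine/coarse partitions covering the event
#'   pixels; masked or unpartitioned pixels are ignored.
#' @param lags A [multitau_lags()] table; built from the events by
#'   default.
#' @param chunk_pixels Pixels densified per block (memory control only;
#'   does not affect results).
#' @return A `corr_accumulator`: list with `lags`, `pixels` (pixel, q,
#'   fine, coarse), matrices `g2_sum`, `if_sum`, `ip_sum`
#'   (pixels x lags), per-lag pair-count `weights`, `n_frames`,
#'   `frame_rate_hz` and `n_repeats = 1`.
#' @export
correlate_multitau <- function(events, qmap, lags = NULL,
                               chunk_pixels = 256L) {
  nf <- n_frames(events)
  if (is.null(lags)) lags <- multitau_lags(nf, frame_rate(events))
  keep <- qmap$mask & !is.na(qmap$fine)
  pixels <- tibble(pixel = qmap$pixel[keep], q = qmap$q[keep],
                   fine = qmap$fine[keep], coarse = qmap$coarse[keep])
  if (nrow(pixels) == 0L) {
    abort("Q map leaves no usable pixels.", class = "saxpcs_invalid_input")
  }
  if (!all(events$pixel %in% qmap$pixel)) {
    abort("Events reference pixels absent from the Q map.",
          class = "saxpcs_invalid_input")
  }

  feasible <- lags$lag_frames < nf &
    lags$channel < nf %/% (2L^lags$level)
  if (!all(feasible)) {
    warn(sprintf("%d lag(s) at or beyond the sequence length dropped.",
                 sum(!feasible)))
    lags <- lags[feasible, ]
  }
  nl <- nrow(lags)
  levels_used <- sort(unique(lags$level))
  npx <- nrow(pixels)
  g2s <- matrix(0, npx, nl)
  ifs <- matrix(0, npx, nl)
  ips <- matrix(0, npx, nl)
  weights <- numeric(nl)

  for (st in seq(1L, npx, by = chunk_pixels)) {
    en <- min(st + chunk_pixels - 1L, npx)
    m <- densify_events(events, pixels$pixel[st:en])
    lev_prev <- 0L
    for (lev in levels_used) {
      while (lev_prev < lev) {
        m <- halve_frames(m)
        lev_prev <- lev_prev + 1L
      }
      tl <- ncol(m)
      sel <- which(lags$level == lev)
      for (i in sel) {
        ch <- lags$channel[i]
        np <- tl - ch
        past <- m[, 1:np, drop = FALSE]
        future <- m[, (ch + 1L):tl, drop = FALSE]
        g2s[st:en, i] <- rowMeans(past * future)
        ifs[st:en, i] <- rowMeans(past)
        ips[st:en, i] <- rowMeans(future)
        weights[i] <- np * 2^lev
      }
    }
  }

  structure(
    list(
      lags = lags, pixels = pixels,
      g2_sum = g2s, if_sum = ifs, ip_sum = ips,
      weights = weights,
      n_frames = nf, frame_rate_hz = frame_rate(events),
      n_repeats = 1L
    ),
    class = "corr_accumulator"
  )
}

#' @export
print.corr_accumulator <- function(x, ...) {
  cat("<corr_accumulator>\n")
  cat(sprintf("  %d pixels, %d fine partitions, %d lags (%.3g - %.3g s), %d repeat(s)\n",
              nrow(x$pixels), length(unique(x$pixels$fine)), nrow(x$lags),
              min(x$lags$lag_s), max(x$lags$lag_s), x$n_repeats))
  invisible(x)
}

#' Average correlator accumulators over repeated measurements
#'
#' Merges repeats by weight-proportional averaging of the unnormalised
#' sums `G2`, `IF`, `IP` per pixel and lag (weights are the pair counts),
#' before any normalisation -- the averaging order required when single
#' repeats are too sparse to normalise individually.
#'
#' @param accs List of `corr_accumulator` objects with identical lag and
#'   pixel structure.
#' @return A single merged `corr_accumulator`; `n_repeats` accumulates.
#' @export
average_accumulators <- function(accs) {
  if (inherits(accs, "corr_accumulator")) accs <- list(accs)
  if (length(accs) == 0L) {
    abort("Need at least one accumulator.", class = "saxpcs_invalid_input")
  }
  ref <- accs[[1]]
  for (a in accs[-1]) {
    if (!identical(a$lags$lag_frames, ref$lags$lag_frames) ||
        !identical(a$pixels$pixel, ref$pixels$pixel) ||
        !identical(a$pixels$fine, ref$pixels$fine)) {
      abort("Accumulators have mismatched lag or pixel structure.",
            class = "saxpcs_structure_error")
    }
  }
  wtot <- Reduce(`+`, lapply(accs, `[[`, "weights"))
  wavg <- function(field) {
    num <- Reduce(`+`, lapply(accs, function(a) {
      sweep(a[[field]], 2L, a$weights, `*`)
    }))
    sweep(num, 2L, wtot, `/`)
  }
  out <- ref
  out$g2_sum <- wavg("g2_sum")
  out$if_sum <- wavg("if_sum")
  out$ip_sum <- wavg("ip_sum")
  out$weights <- wtot
  out$n_repeats <- sum(vapply(accs, `[[`, integer(1), "n_repeats"))
  out
}

#' Flag pixels with abnormally high self-correlation
#'
#' Detector artifacts (e.g. double-counter gating overlap) show up as
#' pixels whose small-lag correlation plateau is far above their
#' neighbours' even when their mean intensity looks normal. Per pixel the
#' plateau statistic is the median of `G2 / (IF * IP)` over the 5
#' smallest lags; within each fine partition, pixels above
#' `median + 5 * 1.4826 * MAD` are flagged. Partitions with fewer than
#' `min_pixels` pixels are skipped with a warning; a degenerate spread
#' (MAD = 0) flags nothing thanks to an epsilon guard.
#'
#' @param acc A `corr_accumulator`.
#' @param n_small_lags Number of smallest lags entering the plateau.
#' @param n_mad Threshold in scaled-MAD units.
#' @param min_pixels Minimum partition size for flagging.
#' @return Logical vector along `acc$pixels`, `TRUE` = bad pixel.
#' @export
flag_bad_pixels <- function(acc, n_small_lags = 5L, n_mad = 5,
                            min_pixels = 10L) {
  ord <- order(acc$lags$lag_frames)
  sel <- ord[seq_len(min(n_small_lags, length(ord)))]
  denom <- acc$if_sum[, sel, drop = FALSE] * acc$ip_sum[, sel, drop = FALSE]
  ratio <- acc$g2_sum[, sel, drop = FALSE] / denom
  ratio[denom == 0] <- NA
  s <- apply(ratio, 1L, median, na.rm = TRUE)
  flags <- rep(FALSE, nrow(acc$pixels))
  for (idx in split(seq_along(s), acc$pixels$fine)) {
    if (length(idx) < min_pixels) {
      warn(sprintf(
        "Fine partition with %d pixels (< %d): bad-pixel flagging skipped.",
        length(idx), min_pixels))
      next
    }
    sv <- s[idx]
    med <- median(sv, na.rm = TRUE)
    spread <- mad(sv, na.rm = TRUE)
    eps <- 1e-12 * max(1, abs(med))
    thr <- med + n_mad * max(spread, eps)
    flags[idx] <- !is.na(sv) & sv > thr
  }
  flags
}

#' Normalised intensity autocorrelation g2(tau, Q)
#'
#' Turns correlator sums into `g2`. Within each fine partition the pixel
#' binning is performed on `G2`, `IF` and `IP` *before* the division:
#' `g2_fine = <G2>_pixels / (<IF>_pixels <IP>_pixels)`. Fine results are
#' then binned into coarse partitions by a pixel-count-weighted mean.
#' The error bar is the standard deviation of g2-per-pixel (pixel-wise
#' division) across all pixels of the coarse partition -- a population
#' spread by default, `error = "sem"` divides by `sqrt(n)`. Cells whose
#' binned `IF` or `IP` vanish are reported missing (`NA`), never
#' infinite.
#'
#' @param acc A `corr_accumulator` (typically after
#'   [average_accumulators()]).
#' @param flags Optional logical bad-pixel vector from
#'   [flag_bad_pixels()]; flagged pixels are excluded everywhere.
#' @param error `"population"` or `"sem"`.
#' @param beta Optional coherence factor recorded on the result for
#'   downstream fits.
#' @return A `g2_result` tibble (`coarse`, `q`, `lag_frames`, `delay_s`,
#'   `g2`, `sigma_g2`, `n_pixels`) with per-fine-partition diagnostics in
#'   `attr(, "fine")`.
#' @export
normalize_g2 <- function(acc, flags = NULL, error = c("population", "sem"),
                         beta = NA_real_) {
  error <- match.arg(error)
  if (is.null(flags)) flags <- rep(FALSE, nrow(acc$pixels))
  use <- !flags
  if (!any(use)) {
    abort("All pixels flagged; nothing to normalise.",
          class = "saxpcs_invalid_input")
  }
  lags <- acc$lags
  nl <- nrow(lags)
  px <- acc$pixels

  # per-pixel g2 (pixel-wise division) for the error estimate
  denom_pp <- acc$if_sum * acc$ip_sum
  g2_pp <- acc$g2_sum / denom_pp
  g2_pp[denom_pp == 0] <- NA

  fine_groups <- split(which(use), px$fine[use])
  fine_tab <- purrr::map_dfr(names(fine_groups), function(f) {
    idx <- fine_groups[[f]]
    mg2 <- colMeans(acc$g2_sum[idx, , drop = FALSE])
    mif <- colMeans(acc$if_sum[idx, , drop = FALSE])
    mip <- colMeans(acc$ip_sum[idx, , drop = FALSE])
    den <- mif * mip
    g2 <- ifelse(den > 0, mg2 / den, NA_real_)
    tibble(fine = as.integer(f), coarse = px$coarse[idx[1]],
           q = mean(px$q[idx]), n_pixels = length(idx),
           lag_frames = lags$lag_frames, delay_s = lags$lag_s, g2 = g2)
  })

  coarse_groups <- split(which(use), px$coarse[use])
  out <- purrr::map_dfr(names(coarse_groups), function(cc) {
    idx <- coarse_groups[[cc]]
    sub <- fine_tab[fine_tab$coarse == as.integer(cc), ]
    g2c <- vapply(seq_len(nl), function(l) {
      s <- sub[sub$lag_frames == lags$lag_frames[l], ]
      ok <- !is.na(s$g2)
      if (!any(ok)) return(NA_real_)
      sum(s$g2[ok] * s$n_pixels[ok]) / sum(s$n_pixels[ok])
    }, numeric(1))
    sig <- vapply(seq_len(nl), function(l) {
      v <- g2_pp[idx, l]
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      if (error == "population") pop_sd(v) else pop_sd(v) / sqrt(length(v))
    }, numeric(1))
    tibble(coarse = as.integer(cc), q = mean(px$q[idx]),
           lag_frames = lags$lag_frames, delay_s = lags$lag_s,
           g2 = g2c, sigma_g2 = sig, n_pixels = length(idx))
  })
  out <- dplyr::arrange(out, .data$q, .data$lag_frames)
  attr(out, "fine") <- fine_tab
  attr(out, "lags") <- lags
  attr(out, "n_repeats") <- acc$n_repeats
  attr(out, "error_type") <- error
  attr(out, "beta_used") <- beta
  attr(out, "n_flagged") <- sum(flags)
  class(out) <- c("g2_result", class(tibble()))
  out
}
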