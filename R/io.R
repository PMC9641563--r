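# Plain-text containers: a TSV body preceded by '#!' header lines, the
# second of which carries the attributes as one JSON object. Simulated
# and recorded data use the same layout, so they are interchangeable.

container_header <- function(kind, attrs) {
  c(sprintf("#! saxpcs %s v1", kind),
    paste0("#! ", jsonlite::toJSON(attrs, auto_unbox = TRUE, digits = NA,
                                   null = "null")))
}

read_container <- function(path, kind) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1], paste0("#! saxpcs ", kind))) {
    abort(sprintf("`%s` is not a saxpcs %s container.", path, kind),
          class = "saxpcs_io_error")
  }
  attrs <- jsonlite::fromJSON(sub("^#! ", "", lines[2]))
  body <- utils::read.delim(path, comment.char = "#", sep = "\t",
                            header = TRUE, check.names = FALSE)
  list(attrs = attrs, body = as_tibble(body))
}

#' Read and write sparse photon-event containers
#'
#' Events are stored as a tab-separated table (`frame_index`,
#' `pixel_index`, `count`) with the sequence attributes (`n_frames`,
#' `n_pixels`, `frame_rate_hz`, per-pixel `q` ring table, seed) in a JSON
#' header line, so a round trip is lossless.
#'
#' @param events A [photon_events] object.
#' @param path File path.
#' @return `read_photon_events()` returns a [photon_events] object;
#'   `write_photon_events()` returns `path` invisibly.
#' @export
write_photon_events <- function(events, path) {
  attrs <- list(
    n_frames = n_frames(events),
    n_pixels = n_pixels(events),
    frame_rate_hz = frame_rate(events),
    pixel_q = pixel_q(events),
    seed = attr(events, "seed")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(container_header("photon_events", attrs), con)
  writeLines("frame_index\tpixel_index\tcount", con)
  if (nrow(events) > 0) {
    writeLines(paste(events$frame, events$pixel, events$count, sep = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_photon_events
#' @export
read_photon_events <- function(path) {
  x <- read_container(path, "photon_events")
  df <- tibble(frame = as.integer(x$body$frame_index),
               pixel = as.integer(x$body$pixel_index),
               count = as.integer(x$body$count))
  new_photon_events(df, x$attrs$n_frames, x$attrs$n_pixels,
                    x$attrs$frame_rate_hz,
                    pixel_q = if (is.null(x$attrs$pixel_q)) NULL
                              else as.numeric(x$attrs$pixel_q),
                    seed = x$attrs$seed)
}

#' Read and write 1D SAXS curves as plain text
#'
#' Four tab-separated columns: `q` (nm^-1), `intensity`, `sigma`,
#' `n_pixels`.
#'
#' @param curve A `saxs_curve` tibble.
#' @param path File path.
#' @return `read_saxs_curve()` returns a `saxs_curve`;
#'   `write_saxs_curve()` returns `path` invisibly.
#' @export
write_saxs_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(container_header("saxs_curve", list(n_bins = nrow(curve))), con)
  writeLines("q\tintensity\tsigma\tn_pixels", con)
  writeLines(paste(format(curve$q, digits = 15),
                   format(curve$intensity, digits = 15),
                   format(curve$sigma, digits = 15),
                   curve$n_pixels, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_saxs_curve
#' @export
read_saxs_curve <- function(path) {
  x <- read_container(path, "saxs_curve")
  new_saxs_curve(tibble(q = x$body$q, intensity = x$body$intensity,
                        sigma = x$body$sigma,
                        n_pixels = as.integer(x$body$n_pixels)))
}

#' Read and write g2 results as plain text
#'
#' Long-format table of the normalised autocorrelation per coarse Q
#' partition and delay, with the lag structure and provenance in the JSON
#' header.
#'
#' @param g2res A `g2_result` from [normalize_g2()].
#' @param path File path.
#' @return `read_g2_result()` returns a `g2_result` (without the
#'   per-fine-partition diagnostics); `write_g2_result()` returns `path`
#'   invisibly.
#' @export
write_g2_result <- function(g2res, path) {
  attrs <- list(
    n_repeats = attr(g2res, "n_repeats"),
    error_type = attr(g2res, "error_type"),
    beta_used = attr(g2res, "beta_used"),
    n_flagged = attr(g2res, "n_flagged")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(container_header("g2_result", attrs), con)
  writeLines("coarse\tq\tlag_frames\tdelay_s\tg2\tsigma_g2\tn_pixels", con)
  writeLines(paste(g2res$coarse, format(g2res$q, digits = 15),
                   g2res$lag_frames, format(g2res$delay_s, digits = 15),
                   format(g2res$g2, digits = 15),
                   format(g2res$sigma_g2, digits = 15),
                   g2res$n_pixels, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_g2_result
#' @export
read_g2_result <- function(path) {
  x <- read_container(path, "g2_result")
  out <- tibble(coarse = as.integer(x$body$coarse), q = x$body$q,
                lag_frames = as.integer(x$body$lag_frames),
                delay_s = x$body$delay_s, g2 = x$body$g2,
                sigma_g2 = x$body$sigma_g2,
                n_pixels = as.integer(x$body$n_pixels))
  attr(out, "n_repeats") <- x$attrs$n_repeats
  attr(out, "error_type") <- x$attrs$error_type
  attr(out, "beta_used") <- x$attrs$beta_used
  attr(out, "n_flagged") <- x$attrs$n_flagged
  class(out) <- c("g2_result", class(tibble()))
  out
}

#' Read and write detector geometry as a YAML block
#'
#' Keys: `pixel_pitch_um`, `distance_m`, `energy_kev`, `beam_center`,
#' `frame_rate_hz`, `shape`.
#'
#' @param geometry A [detector_geometry()].
#' @param path File path.
#' @return `read_geometry()` returns a [detector_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geometry, path) {
  yaml::write_yaml(
    list(pixel_pitch_um = geometry$pixel_pitch_um,
         distance_m = geometry$distance_m,
         energy_kev = geometry$energy_kev,
         beam_center = geometry$beam_center,
         frame_rate_hz = geometry$frame_rate_hz,
         shape = as.integer(geometry$shape)),
    path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  detector_geometry(y$pixel_pitch_um, y$distance_m, y$energy_kev,
                    y$beam_center, y$frame_rate_hz, y$shape)
}
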