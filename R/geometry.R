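#' X-ray wavelength from photon energy
#'
#' @param energy_kev Photon energy in keV.
#' @return Wavelength in Angstrom, `12.3984 / energy_kev`.
#' @examples
#' wavelength_from_energy(10.94)
#' @export
wavelength_from_energy <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) ||
      any(energy_kev <= 0)) {
    abort("`energy_kev` must be finite and positive.",
          class = "saxpcs_invalid_input")
  }
  hc_kev_angstrom / energy_kev
}

#' Detector geometry for a small-angle scattering setup
#'
#' Bundles the quantities needed to map detector pixels to momentum
#' transfer Q: pixel pitch, sample-detector distance, photon energy
#' (wavelength is derived), beam center, frame rate and detector shape.
#' Pixel coordinates are 0-based `(row, col)`; the beam center may be
#' fractional.
#'
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param distance_m Sample-detector distance in metres.
#' @param energy_kev Photon energy in keV.
#' @param beam_center Numeric length-2, `(row, col)` of the direct beam in
#'   fractional 0-based pixel coordinates.
#' @param frame_rate_hz Detector frame rate in Hz.
#' @param shape Integer length-2, `(n_rows, n_cols)` of the detector.
#' @return A `detector_geometry` object (list with the fields above plus
#'   `wavelength_a`, the wavelength in Angstrom).
#' @examples
#' detector_geometry(76, 8, 10.94, c(256.5, 256.5), 52000, c(512, 512))
#' @export
detector_geometry <- function(pixel_pitch_um, distance_m, energy_kev,
                              beam_center, frame_rate_hz, shape) {
  check_positive_scalar(pixel_pitch_um, "pixel_pitch_um")
  check_positive_scalar(distance_m, "distance_m")
  check_positive_scalar(energy_kev, "energy_kev")
  check_positive_scalar(frame_rate_hz, "frame_rate_hz")
  if (length(beam_center) != 2L || any(!is.finite(beam_center))) {
    abort("`beam_center` must be two finite numbers (row, col).",
          class = "saxpcs_invalid_input")
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    abort("`shape` must be two positive integers (n_rows, n_cols).",
          class = "saxpcs_invalid_input")
  }
  structure(
    list(
      pixel_pitch_um = pixel_pitch_um,
      distance_m = distance_m,
      energy_kev = energy_kev,
      wavelength_a = wavelength_from_energy(energy_kev),
      beam_center = as.numeric(beam_center),
      frame_rate_hz = frame_rate_hz,
      shape = shape
    ),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("<detector_geometry>\n")
  cat(sprintf("  shape       : %d x %d pixels, pitch %.1f um\n",
              x$shape[1], x$shape[2], x$pixel_pitch_um))
  cat(sprintf("  distance    : %.3f m\n", x$distance_m))
  cat(sprintf("  energy      : %.4g keV (lambda = %.4f A)\n",
              x$energy_kev, x$wavelength_a))
  cat(sprintf("  beam center : (%.2f, %.2f)  [0-based row, col]\n",
              x$beam_center[1], x$beam_center[2]))
  cat(sprintf("  frame rate  : %.5g Hz\n", x$frame_rate_hz))
  invisible(x)
}

new_qmap <- function(df, geometry = NULL, partitions = NULL) {
  out <- as_tibble(df)
  attr(out, "geometry") <- geometry
  attr(out, "partitions") <- partitions
  class(out) <- c("qmap", class(tibble()))
  out
}

#' Per-pixel momentum-transfer map
#'
#' Maps every detector pixel to its momentum transfer
#' `Q = (4 pi / lambda) sin(theta / 2)` with `theta = atan(r / L)`, where
#' `r` is the radial distance of the pixel from the beam center and `L`
#' the sample-detector distance. The exact formula is used rather than the
#' small-angle approximation `2 pi r / (L lambda)`, although at
#' small-angle geometries they agree to high precision.
#'
#' @param geometry A [detector_geometry()].
#' @param mask Logical matrix of the detector shape, `TRUE` for usable
#'   pixels. Defaults to all usable.
#' @return A `qmap`: a tibble with one row per pixel and columns `pixel`
#'   (0-based linear index, row-major), `row`, `col` (0-based), `q`
#'   (nm^-1) and `mask`. Partition labels are added by
#'   [make_partitions()].
#' @export
build_qmap <- function(geometry, mask = NULL) {
  if (!inherits(geometry, "detector_geometry")) {
    abort("`geometry` must be a detector_geometry object.",
          class = "saxpcs_invalid_input")
  }
  nr <- geometry$shape[1]
  nc <- geometry$shape[2]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!identical(dim(mask), c(nr, nc))) {
    abort("`mask` shape must equal the geometry shape.",
          class = "saxpcs_invalid_input")
  }
  bc <- geometry$beam_center
  if (bc[1] < -10 * nr || bc[1] > 11 * nr || bc[2] < -10 * nc ||
      bc[2] > 11 * nc) {
    abort("Beam center is far outside the detector bounding box.",
          class = "saxpcs_invalid_geometry")
  }
  # row-major 0-based linear index: pixel = row * n_cols + col
  row <- rep(0:(nr - 1L), each = nc)
  col <- rep(0:(nc - 1L), times = nr)
  pitch_m <- geometry$pixel_pitch_um * 1e-6
  r_m <- pitch_m * sqrt((row - bc[1])^2 + (col - bc[2])^2)
  theta <- atan(r_m / geometry$distance_m)
  q_nm <- (4 * pi / geometry$wavelength_a) * sin(theta / 2) * 10
  mask_vec <- as.vector(t(mask))
  new_qmap(
    tibble(
      pixel = row * nc + col,
      row = row, col = col,
      q = q_nm,
      mask = mask_vec
    ),
    geometry = geometry
  )
}

#' Q-map for a set of discrete rings
#'
#' Builds a `qmap` for ring-style data where pixels are listed per Q value
#' (the layout the synthetic speckle generator emits): each ring is its
#' own fine and coarse partition, so the correlator's per-partition
#' averages are per-ring averages.
#'
#' @param q Numeric vector of ring momentum transfers (nm^-1), strictly
#'   increasing.
#' @param n_pixels Integer vector, pixels per ring (recycled if scalar).
#' @param frame_rate_hz Frame rate carried along for delay-time
#'   conversion.
#' @return A `qmap` with one row per pixel and fine/coarse/saxs labels set
#'   to the (0-based) ring index.
#' @export
ring_qmap <- function(q, n_pixels, frame_rate_hz = 52000) {
  if (any(diff(q) <= 0)) {
    abort("Ring `q` values must be strictly increasing.",
          class = "saxpcs_invalid_input")
  }
  n_pixels <- rep_len(as.integer(n_pixels), length(q))
  if (any(n_pixels < 1L)) {
    abort("`n_pixels` must be >= 1 for every ring.",
          class = "saxpcs_invalid_input")
  }
  ring <- rep(seq_along(q) - 1L, times = n_pixels)
  total <- sum(n_pixels)
  tab <- tibble(label = seq_along(q) - 1L, q = q, n_pixels = n_pixels)
  new_qmap(
    tibble(
      pixel = 0:(total - 1L),
      row = NA_integer_, col = NA_integer_,
      q = rep(q, times = n_pixels),
      mask = TRUE,
      fine = ring, coarse = ring, saxs = ring
    ),
    geometry = list(frame_rate_hz = frame_rate_hz, ring = TRUE),
    partitions = list(
      fine = tab, coarse = tab, saxs = tab,
      fine_width = NA_real_, rebin_factor = 1L, n_saxs = length(q),
      saxs_edges = NULL
    )
  )
}

partition_table <- function(df, label_col) {
  lab <- df[[label_col]]
  keep <- df$mask & !is.na(lab)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(label = lab[keep], q = df$q[keep]), .data$label),
    q = mean(.data$q), n_pixels = dplyr::n(), .groups = "drop"
  )
  dplyr::arrange(agg, .data$label)
}

#' Attach fine, coarse and SAXS partitions to a Q map
#'
#' Fine partitions are contiguous Q bins of constant width starting at the
#' minimum unmasked Q (partial trailing bins are kept); coarse partitions
#' group `rebin_factor` consecutive fine bins
#' (`coarse = fine %/% rebin_factor`); SAXS partitions are `n_saxs`
#' logarithmically spaced bins between the smallest positive and largest
#' unmasked Q. Representative Q per partition is the mean over member
#' pixels, consistent with how intensities are averaged.
#'
#' @param qmap A `qmap` from [build_qmap()].
#' @param fine_width Fine partition width in nm^-1. The default
#'   1e-3 nm^-1 is about two pixels at an 8 m small-angle geometry.
#' @param rebin_factor How many fine partitions form one coarse partition.
#' @param n_saxs Number of log-spaced SAXS bins.
#' @return The `qmap` with integer label columns `fine`, `coarse`, `saxs`
#'   (`NA` for masked pixels) and a `partitions` attribute holding per-
#'   partition tables (`label`, `q`, `n_pixels`) and the SAXS bin edges.
#' @export
make_partitions <- function(qmap, fine_width = 1e-3, rebin_factor = 10L,
                            n_saxs = 270L) {
  check_positive_scalar(fine_width, "fine_width")
  rebin_factor <- as.integer(rebin_factor)
  n_saxs <- as.integer(n_saxs)
  if (rebin_factor < 1L || n_saxs < 1L) {
    abort("`rebin_factor` and `n_saxs` must be >= 1.",
          class = "saxpcs_invalid_input")
  }
  qu <- qmap$q[qmap$mask]
  if (length(unique(qu)) < 2L) {
    abort("Need at least 2 distinct unmasked Q values to partition.",
          class = "saxpcs_partition_error")
  }
  qmin <- min(qu)
  fine <- ifelse(qmap$mask, pmax(0L, floor((qmap$q - qmin) / fine_width)),
                 NA_integer_)
  fine <- as.integer(fine)
  coarse <- fine %/% rebin_factor

  qpos <- qu[qu > 0]
  edges <- exp(seq(log(min(qpos)), log(max(qu)), length.out = n_saxs + 1L))
  saxs <- rep(NA_integer_, nrow(qmap))
  ok <- qmap$mask & qmap$q >= edges[1]
  saxs[ok] <- pmin(findInterval(qmap$q[ok], edges,
                                rightmost.closed = TRUE) - 1L,
                   n_saxs - 1L)

  out <- qmap
  out$fine <- fine
  out$coarse <- coarse
  out$saxs <- saxs
  attr(out, "partitions") <- list(
    fine = partition_table(out, "fine"),
    coarse = partition_table(out, "coarse"),
    saxs = partition_table(out, "saxs"),
    fine_width = fine_width,
    rebin_factor = rebin_factor,
    n_saxs = n_saxs,
    saxs_edges = edges
  )
  out
}

#' Partition tables of a Q map
#'
#' @param qmap A `qmap` with partitions attached.
#' @param which One of `"fine"`, `"coarse"`, `"saxs"`; `NULL` returns the
#'   full partitions attribute.
#' @return A tibble (`label`, `q`, `n_pixels`) or the full list.
#' @export
partitions <- function(qmap, which = NULL) {
  p <- attr(qmap, "partitions")
  if (is.null(p)) {
    abort("Q map has no partitions; call make_partitions() first.",
          class = "saxpcs_invalid_input")
  }
  if (is.null(which)) p else p[[match.arg(which, c("fine", "coarse", "saxs"))]]
}
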