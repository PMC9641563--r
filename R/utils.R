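#' Concentration after mixing stock with diluent
#'
#' Volumetric dilution: `parts_stock` volumes of stock mixed with
#' `parts_diluent` volumes of diluent give
#' `stock * parts_stock / (parts_stock + parts_diluent)`.
#'
#' @param stock Stock concentration (any unit).
#' @param parts_stock,parts_diluent Volume parts of stock and diluent
#'   (e.g. a 7:1 mix is `parts_stock = 7, parts_diluent = 1`).
#' @return Concentration of the mixture, same unit as `stock`.
#' @examples
#' dilute_concentration(10.96, 7, 1)
#' @export
dilute_concentration <- function(stock, parts_stock, parts_diluent) {
  if (any(stock < 0) || parts_stock <= 0 || parts_diluent < 0) {
    abort("`stock` must be >= 0, `parts_stock` > 0, `parts_diluent` >= 0.",
          class = "saxpcs_invalid_input")
  }
  stock * parts_stock / (parts_stock + parts_diluent)
}

#' Total duration of a frame sequence
#'
#' @param events A [photon_events] object.
#' @return Duration in seconds, `n_frames / frame_rate`.
#' @export
sequence_duration <- function(events) {
  n_frames(events) / frame_rate(events)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite positive number.", name),
          class = "saxpcs_invalid_input")
  }
  invisible(x)
}
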