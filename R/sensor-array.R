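#' Default 64-channel circular sensor array
#'
#' Planar grid of 64 magnetometers measuring the field component normal to
#' the sensor plane (Bz), arranged on concentric rings above the anterior
#' thorax at a common standoff height.
#'
#' @param radii Ring radii in metres (one ring of `per_ring` sensors each).
#' @param per_ring Sensors per ring.
#' @param standoff Chest-to-sensor distance in metres (z of every sensor).
#' @return A tibble of class `mcg_sensor_array` with columns `channel`, `x`,
#'   `y`, `z` and attributes `component = "Bz"` and `standoff`.
#' @export
default_sensor_array <- function(radii = c(0.035, 0.07, 0.105, 0.14),
                                 per_ring = 16L, standoff = 0.01) {
  stopifnot(standoff > 0, all(radii > 0))
  rows <- purrr::imap(radii, function(r, i) {
    ## alternate rings are rotated half a step so no two sensors coincide
    ang <- 2 * pi * (seq_len(per_ring) - 1L) / per_ring +
      (i %% 2L) * pi / per_ring
    tibble::tibble(x = r * cos(ang), y = r * sin(ang), z = standoff)
  })
  arr <- dplyr::bind_rows(rows)
  arr <- dplyr::mutate(arr, channel = dplyr::row_number(), .before = 1)
  n <- nrow(arr)
  if (anyDuplicated(round(arr[, c("x", "y")], 12)) > 0) {
    stop("sensor positions are not distinct")
  }
  structure(arr, component = "Bz", standoff = standoff,
            class = c("mcg_sensor_array", class(arr)))
}

## n x 3 position matrix from a sensor-array tibble
sensor_positions <- function(arr) {
  cbind(arr$x, arr$y, arr$z)
}
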