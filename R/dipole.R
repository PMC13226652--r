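## Free-space current-dipole forward model. For a dipole moment p (A*m) at
## r0, the magnetic field at r is B = mu0/(4 pi) * p x (r - r0) / |r - r0|^3;
## the sensors measure its z-component. For a horizontally layered conductor
## the normal component is dominated by primary currents, so volume currents
## are omitted.

MU0_OVER_4PI <- 1e-7  # T m / (A m)

#' Current-dipole Bz at a sensor
#'
#' @param moment Dipole moment, length-3 numeric (A·m).
#' @param source_pos Dipole position, length-3 numeric (m).
#' @param sensor_pos Sensor position, length-3 numeric (m).
#' @return The z-component of the dipole field (Tesla). Linear in `moment`.
#' @export
dipole_bz <- function(moment, source_pos, sensor_pos) {
  stopifnot(length(moment) == 3, length(source_pos) == 3,
            length(sensor_pos) == 3)
  d <- sensor_pos - source_pos
  r <- sqrt(sum(d^2))
  if (r == 0) stop("sensor coincides with the source")
  ## z-component of p x d
  MU0_OVER_4PI * (moment[1] * d[2] - moment[2] * d[1]) / r^3
}

#' Lead-field matrix for Bz
#'
#' Rows map a dipole moment vector to the Bz reading of each sensor:
#' `Bz = L %*% p`. The z-component of the moment never contributes to Bz of a
#' free-space dipole, so the third column is zero.
#'
#' @param arr An `mcg_sensor_array`.
#' @param source_pos Dipole position, length-3 (m).
#' @return `n_sensors x 3` matrix (Tesla per A·m).
#' @export
leadfield_bz <- function(arr, source_pos) {
  pos <- sensor_positions(arr)
  d <- sweep(pos, 2, source_pos)
  r3 <- (rowSums(d^2))^(3 / 2)
  if (any(r3 == 0)) stop("a sensor coincides with the source")
  MU0_OVER_4PI * cbind(d[, 2] / r3, -d[, 1] / r3, 0)
}
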