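#' Conditioning chamber configuration
#'
#' Describes the 1-D shuttle chamber: a narrow corridor in which a single
#' walking bee is tracked by a row of equally spaced photo sensors. Positions
#' are expressed in cm on a symmetric axis with 0 at the chamber midline, the
#' left end negative and the right end positive, so the default chamber spans
#' -7.4 to +7.4 cm.
#'
#' @param length_cm Interior length of the corridor in cm.
#' @param width_cm Interior width in cm (metadata; movement is 1-D).
#' @param depth_cm Interior depth in cm (metadata).
#' @param n_sensors Number of photo sensors spread evenly along the length.
#' @param sampling_rate_hz Position sampling rate in Hz.
#'
#' @return An object of class `apis_chamber`: a list with the fields above
#'   plus `position_min` / `position_max` (the +/- half length) and
#'   `sensor_pitch` (`length_cm / n_sensors`).
#' @examples
#' ch <- apis_chamber()
#' ch$position_max      # 7.4
#' sensor_centers(ch)   # 26 sensor center coordinates
#' @export
apis_chamber <- function(length_cm = 14.8, width_cm = 2.0, depth_cm = 0.6,
                         n_sensors = 26L, sampling_rate_hz = 5.0) {
  stopifnot(is.numeric(length_cm), length_cm > 0,
            is.numeric(n_sensors), n_sensors >= 2,
            is.numeric(sampling_rate_hz), sampling_rate_hz > 0)
  half <- length_cm / 2
  structure(list(
    length_cm = length_cm,
    width_cm = width_cm,
    depth_cm = depth_cm,
    n_sensors = as.integer(n_sensors),
    sampling_rate_hz = sampling_rate_hz,
    position_min = -half,
    position_max = half,
    sensor_pitch = length_cm / n_sensors
  ), class = "apis_chamber")
}

#' @export
print.apis_chamber <- function(x, ...) {
  cat(sprintf(
    "<apis_chamber> %.1f x %.1f x %.1f cm, %d sensors (pitch %.3f cm), %g Hz\n",
    x$length_cm, x$width_cm, x$depth_cm, x$n_sensors, x$sensor_pitch,
    x$sampling_rate_hz))
  invisible(x)
}

#' Photo sensor center coordinates
#'
#' The i-th of `n` sensors covers the interval
#' `[position_min + (i-1) * pitch, position_min + i * pitch]`; its center is
#' the coordinate reported whenever the bee is within that interval, so the
#' quantization error of a logged position is at most half a pitch.
#'
#' @param chamber An [apis_chamber()].
#' @return Numeric vector of `n_sensors` coordinates in cm.
#' @export
sensor_centers <- function(chamber) {
  i <- seq_len(chamber$n_sensors) - 1
  chamber$position_min + (i + 0.5) * chamber$sensor_pitch
}

# Validate a position vector against the chamber bounds; returns indices of
# offending entries (empty when all inside).
position_violations <- function(x, chamber, tol = 1e-9) {
  which(!is.na(x) &
          (x < chamber$position_min - tol | x > chamber$position_max + tol))
}
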