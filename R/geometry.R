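#' Wind-tunnel working-section geometry
#'
#' Describes the tracked working section of a laminar-flow wind tunnel.
#' The coordinate convention places the origin at the centre of the
#' working-section floor, with +x downwind, +y cross-wind and +z up, all in
#' centimetres. Defaults match a 224 x 61 x 61 cm section with a 40 cm/s
#' laminar flow and 60 Hz tracking.
#'
#' @param length,width,height Working-section dimensions in cm.
#' @param wind_speed Laminar flow speed in cm/s.
#' @param frame_rate Tracking frame rate in Hz.
#' @return An object of class `tv_geometry`.
#' @examples
#' tunnel_geometry()
#' @export
tunnel_geometry <- function(length = 224, width = 61, height = 61,
                            wind_speed = 40, frame_rate = 60) {
  vals <- c(length = length, width = width, height = height,
            wind_speed = wind_speed, frame_rate = frame_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry fields must be finite and > 0")
  }
  structure(
    list(length = length, width = width, height = height,
         wind_speed = wind_speed, frame_rate = frame_rate),
    class = "tv_geometry"
  )
}

#' @export
print.tv_geometry <- function(x, ...) {
  cat(sprintf(
    "<tunnel geometry> %g x %g x %g cm, wind %g cm/s, tracking %g Hz\n",
    x$length, x$width, x$height, x$wind_speed, x$frame_rate))
  invisible(x)
}

# axis-aligned bounds of the working section under the floor-centre origin
geometry_bounds <- function(geometry) {
  list(x = c(-geometry$length / 2, geometry$length / 2),
       y = c(-geometry$width / 2, geometry$width / 2),
       z = c(0, geometry$height))
}

#' Peak wavelengths of the LED stimulus channels
#'
#' The stimulus synthesizers carry 17 narrowband LED channels with peak
#' wavelengths spanning 390-743 nm. Channels may also be symbolic
#' achromatic stimuli: `"gray"`, `"neutral_gray"` or `"black_tulle"`.
#'
#' @return Numeric vector of 17 peak wavelengths (nm).
#' @export
led_channel_wavelengths <- function() {
  c(390, 410, 435, 450, 478, 500, 527, 552, 575, 600,
    621, 645, 660, 680, 700, 720, 743)
}

symbolic_channels <- function() c("gray", "neutral_gray", "black_tulle")

# validate a channel label; numeric channels must fall in the LED gamut
validate_channel <- function(channel) {
  chr <- as.character(channel)
  num <- suppressWarnings(as.numeric(chr))
  ok <- ifelse(is.na(num),
               chr %in% symbolic_channels(),
               num >= 390 & num <= 743)
  if (!all(ok)) {
    abort(sprintf(
      "unknown channel(s): %s. Valid channels are wavelengths in [390, 743] nm or one of: %s",
      paste(unique(chr[!ok]), collapse = ", "),
      paste(symbolic_channels(), collapse = ", ")))
  }
  invisible(channel)
}

#' Cylindrical response volume over a floor stimulus
#'
#' Approach to a floor-projected stimulus is scored by passage through a
#' fictive vertical cylinder centred over the stimulus, 14 cm in diameter
#' and 4 cm tall by default, with its base on the tunnel floor.
#'
#' @param center_x,center_y Centre of the cylinder on the floor (cm).
#' @param diameter Cylinder diameter (cm).
#' @param height Cylinder height (cm).
#' @param z_base Height of the cylinder base above the floor (cm).
#' @return An object of class `tv_volume`.
#' @examples
#' response_volume(-56, -15)
#' @export
response_volume <- function(center_x, center_y, diameter = 14, height = 4,
                            z_base = 0) {
  if (diameter <= 0 || height <= 0) abort("diameter and height must be > 0")
  structure(
    list(center_x = center_x, center_y = center_y, diameter = diameter,
         height = height, z_base = z_base),
    class = "tv_volume"
  )
}

#' @export
print.tv_volume <- function(x, ...) {
  cat(sprintf("<response volume> centre (%g, %g) cm, d=%g cm, h=%g cm, base z=%g cm\n",
              x$center_x, x$center_y, x$diameter, x$height, x$z_base))
  invisible(x)
}

# point-in-cylinder membership; boundary inclusive (<=) for determinism
in_volume <- function(x, y, z, volume) {
  r2 <- (x - volume$center_x)^2 + (y - volume$center_y)^2
  r2 <= (volume$diameter / 2)^2 &
    z >= volume$z_base &
    z <= volume$z_base + volume$height
}

# the test/control cylinders must not overlap for the preference index to
# be well defined
check_disjoint <- function(test_volume, control_volume) {
  sep <- sqrt((test_volume$center_x - control_volume$center_x)^2 +
                (test_volume$center_y - control_volume$center_y)^2)
  if (sep <= (test_volume$diameter + control_volume$diameter) / 2) {
    abort(sprintf(
      "test and control volumes overlap (centre separation %.2f cm)", sep))
  }
  invisible(TRUE)
}

# default symmetric stimulus placement about y = 0, upwind third of the floor
default_stimulus_positions <- function() {
  list(test = c(x = -56, y = -15.25), control = c(x = -56, y = 15.25))
}
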