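# Static/dynamic acceleration split, pitch & roll, tilt compensation and
# declination-corrected compass heading.

#' Axis map aligning sensor coordinate frames
#'
#' The magnetometer and accelerometer frames of a tag are not necessarily
#' aligned, and the device itself may be mounted in any of several discrete
#' orientations on the animal. Both corrections are signed permutations
#' (orthogonal matrices with entries in {-1, 0, 1}); the composed transform
#' is applied to the magnetometer channels (and optionally the accelerometer
#' channels) before attitude and heading are derived.
#'
#' @param mag 3 x 3 signed permutation aligning the magnetometer frame to the
#'   accelerometer frame.
#' @param mount 3 x 3 signed permutation for the device mounting orientation.
#' @return an `axis_map` object.
#' @export
axis_map <- function(mag = diag(3), mount = diag(3)) {
  if (!is_signed_permutation(mag)) stop("'mag' is not a signed permutation matrix")
  if (!is_signed_permutation(mount)) stop("'mount' is not a signed permutation matrix")
  structure(list(mag = mag, mount = mount), class = "axis_map")
}

#' Invert an axis map
#' @param map an [axis_map].
#' @return the inverse map (signed permutations are orthogonal, so the
#'   inverse is the transpose).
#' @export
invert_axis_map <- function(map) {
  stopifnot(inherits(map, "axis_map"))
  # signed permutations are orthogonal: inverse = transpose
  axis_map(mag = t(map$mag), mount = t(map$mount))
}

#' Apply an axis map to the sensor channels of a table
#'
#' @param table a [sensor_table].
#' @param map an [axis_map].
#' @param accel also transform the accelerometer channels by the mount
#'   transform (the magnetometer always receives `mount %*% mag`).
#' @return the table with the sensor channels transformed in place; applying
#'   a map and then its inverse restores the input.
#' @export
apply_axis_map <- function(table, map, accel = TRUE) {
  stopifnot(inherits(map, "axis_map"))
  sc <- schema(table)
  m <- sensor_matrix(table, "mag") %*% t(map$mount %*% map$mag)
  for (ax in 1:3) {
    nm <- sc$name[sc$role == paste0("mag-", c("x", "y", "z")[ax])][1]
    table[[nm]] <- m[, ax]
  }
  if (accel && any(sc$role == "accel-x")) {
    a <- sensor_matrix(table, "accel") %*% t(map$mount)
    for (ax in 1:3) {
      nm <- sc$name[sc$role == paste0("accel-", c("x", "y", "z")[ax])][1]
      table[[nm]] <- a[, ax]
    }
  }
  table
}

#' Static acceleration by windowed moving average
#'
#' Splits raw acceleration into a static (gravity-dominated, low-frequency)
#' part, estimated per axis by a centred [running_mean], and the dynamic
#' residual. The identity `static + dynamic = raw` holds exactly per axis
#' and sample.
#'
#' @param accel N x 3 raw acceleration matrix (g).
#' @param window odd window length in samples; a window spanning about 2 s of
#'   data is a common starting point.
#' @return list with `static` and `dynamic` N x 3 matrices.
#' @export
static_acceleration <- function(accel, window) {
  accel <- as.matrix(accel)
  static <- apply(accel, 2, running_mean, window = window)
  list(static = static, dynamic = accel - static)
}

#' Pitch and roll from static acceleration
#'
#' Standard accelerometer-tilt equations:
#' `pitch = atan2(-sx, sqrt(sy^2 + sz^2))`, `roll = atan2(sy, sz)`,
#' for a tag whose z axis reads +1 g when the device is level. At gimbal
#' lock (|pitch| = 90, so sy = sz = 0) roll is 0 by convention.
#'
#' @param static N x 3 static acceleration matrix.
#' @return data frame with `pitch` (degrees, [-90, 90]) and `roll` (degrees,
#'   (-180, 180]); zero-norm static vectors yield missing values.
#' @export
pitch_roll <- function(static) {
  static <- as.matrix(static)
  nrm <- sqrt(rowSums(static^2))
  pitch <- rad2deg(atan2(-static[, 1], sqrt(static[, 2]^2 + static[, 3]^2)))
  roll <- rad2deg(atan2(static[, 2], static[, 3]))
  bad <- !is.na(nrm) & nrm == 0
  pitch[bad] <- NA_real_
  roll[bad] <- NA_real_
  data.frame(pitch = pitch, roll = roll)
}

#' Rotate magnetometer vectors level with the earth's surface
#'
#' Undoes the device tilt: each magnetometer vector is rotated by roll about
#' the x axis and then by pitch about the y axis, so that its x-y plane is
#' horizontal and the compass equation applies. Pitch and roll may come from
#' [pitch_roll] or from any external source (e.g. a gyroscope).
#'
#' @param mag N x 3 magnetometer matrix (calibrated, device frame).
#' @param attitude data frame with `pitch` and `roll` in degrees.
#' @return N x 3 matrix of level-frame magnetometer vectors; missing
#'   attitude yields missing output rows.
#' @export
tilt_compensate <- function(mag, attitude) {
  mag <- as.matrix(mag)
  stopifnot(nrow(mag) == nrow(attitude))
  th <- deg2rad(attitude$pitch)
  ph <- deg2rad(attitude$roll)
  mx <- mag[, 1]; my <- mag[, 2]; mz <- mag[, 3]
  # roll about x
  v2 <- my * cos(ph) - mz * sin(ph)
  v3 <- my * sin(ph) + mz * cos(ph)
  # pitch about y
  lx <- mx * cos(th) + v3 * sin(th)
  lz <- -mx * sin(th) + v3 * cos(th)
  out <- cbind(lx, v2, lz)
  colnames(out) <- c("x", "y", "z")
  out[is.na(th) | is.na(ph), ] <- NA_real_
  out
}

#' Compass heading from level-frame magnetometer components
#'
#' The magnetic-north heading is `H = atan(m_y / -m_x) * 180 / pi`, evaluated
#' with the two-argument arctangent so all four quadrants resolve, mapped to
#' [0, 360); the declination angle (from a geomagnetic reference table for
#' the study site) is then added modulo 360 to obtain geographic heading.
#'
#' @param level_mag N x 3 (or N x 2) matrix of tilt- and error-corrected
#'   magnetometer components.
#' @param declination declination angle in degrees, |declination| <= 180.
#' @return numeric vector of headings in degrees [0, 360); missing where the
#'   horizontal component vanishes (heading undefined) or inputs are missing.
#' @export
heading <- function(level_mag, declination = 0) {
  stopifnot(abs(declination) <= 180)
  level_mag <- as.matrix(level_mag)
  mx <- level_mag[, 1]; my <- level_mag[, 2]
  h <- wrap360(rad2deg(atan2(my, -mx)) + declination)
  horiz <- sqrt(mx^2 + my^2)
  tot <- sqrt(rowSums(level_mag^2))
  h[!is.na(horiz) & horiz < 1e-9 * pmax(tot, .Machine$double.xmin)] <- NA_real_
  h
}

#' Derive pitch, roll and heading channels for a sensor table
#'
#' Convenience wrapper running the full attitude pipeline: static/dynamic
#' split of the accelerometer channels, pitch/roll, tilt compensation of the
#' (calibrated) magnetometer channels and declination-corrected heading,
#' appending `pitch`, `roll` and `heading` columns.
#'
#' @param table a [sensor_table].
#' @param window odd moving-average window (samples) for the static split.
#' @param declination declination angle in degrees.
#' @param mag_channels optional character vector of three column names to use
#'   as the (calibrated) magnetometer; defaults to the `mag-*` role channels.
#' @return the table with `pitch`, `roll`, `heading` appended.
#' @export
derive_attitude <- function(table, window, declination = 0, mag_channels = NULL) {
  acc <- sensor_matrix(table, "accel")
  m <- if (is.null(mag_channels)) sensor_matrix(table, "mag") else
    as.matrix(as.data.frame(table)[, mag_channels])
  st <- static_acceleration(acc, window)
  att <- pitch_roll(st$static)
  lev <- tilt_compensate(m, att)
  h <- heading(lev, declination)
  append_channels(table, list(pitch = att$pitch, roll = att$roll, heading = h))
}
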