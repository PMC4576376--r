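# Dead-reckoned track integration on the spherical earth and iterative
# correction against ground-truth positional fixes.

#' Mean earth radius used throughout (metres)
#' @export
EARTH_RADIUS <- 6.371e6

#' Great-circle distance between two points (haversine)
#'
#' `arcDist = sin^2(latD/2) + sin^2(lonD/2) cos(lat0) cos(lat1)`;
#' `d = R * 2 * atan2(sqrt(arcDist), sqrt(1 - arcDist))`.
#'
#' @param lat0,lon0,lat1,lon1 coordinates in degrees (vectorised).
#' @param R earth radius in metres.
#' @return distance in metres; symmetric and non-negative.
#' @export
fix_distance <- function(lat0, lon0, lat1, lon1, R = EARTH_RADIUS) {
  p0 <- deg2rad(lat0); p1 <- deg2rad(lat1)
  dlat <- deg2rad(lat1 - lat0)
  dlon <- deg2rad(lon1 - lon0)
  a <- sin(dlat / 2)^2 + sin(dlon / 2)^2 * cos(p0) * cos(p1)
  a <- pmin(pmax(a, 0), 1)
  R * 2 * atan2(sqrt(a), sqrt(1 - a))
}

#' Initial great-circle bearing between two points
#'
#' Two-argument-arctangent bearing from the first point to the second, in
#' [0, 360). It is the heading for which a single dead-reckoning step of the
#' matching angular distance lands on the second point (the round-trip
#' property tying it to [dead_reckon]).
#'
#' @inheritParams fix_distance
#' @return bearing in degrees [0, 360); identical points are an error.
#' @export
fix_heading <- function(lat0, lon0, lat1, lon1) {
  if (any(lat0 == lat1 & lon0 == lon1)) stop("bearing undefined: identical points")
  p0 <- deg2rad(lat0); p1 <- deg2rad(lat1)
  dlon <- deg2rad(lon1 - lon0)
  th <- atan2(sin(dlon) * cos(p1),
              cos(p0) * sin(p1) - sin(p0) * cos(p1) * cos(dlon))
  wrap360(rad2deg(th))
}

# one spherical destination-point step; angles in degrees, q in radians
step_destination <- function(lat, lon, H, q) {
  la0 <- deg2rad(lat)
  h <- deg2rad(H)
  la1 <- asin(sin(la0) * cos(q) + cos(la0) * sin(q) * cos(h))
  lo1 <- deg2rad(lon) +
    atan2(sin(h) * sin(q) * cos(la0), cos(q) - sin(la0) * sin(la1))
  c(rad2deg(la1), wrap180(rad2deg(lo1)))
}

new_geo_track <- function(time_ms, lat, lon, start, R = EARTH_RADIUS) {
  structure(data.frame(time_ms = time_ms, lat = lat, lon = lon),
            start = start, R = R, class = c("geo_track", "data.frame"))
}

#' Dead-reckon a track from heading and speed
#'
#' Integrates per-sample geographic heading and speed into latitude/longitude
#' on the spherical earth. Each sample advances the position by the angular
#' distance `q = s * dt / R` (the speed integrated over the sample interval
#' and converted to radians on an earth of radius `R`) along its heading:
#' `lat_i = asin(sin lat_{i-1} cos q + cos lat_{i-1} sin q cos H)` and
#' `lon_i = lon_{i-1} + atan2(sin H sin q cos lat_{i-1},
#' cos q - sin lat_{i-1} sin lat_i)`. Samples with missing heading or speed
#' carry the position forward unchanged.
#'
#' @param heading per-sample geographic heading in degrees.
#' @param speed per-sample speed in m/s.
#' @param dt sample interval(s) in seconds (scalar or per-sample).
#' @param start `c(lat, lon)` start position in degrees (taken from the
#'   first ground-truth fix when one exists).
#' @param time_ms optional per-sample timestamps carried into the track.
#' @param R earth radius in metres.
#' @return a `geo_track` data frame (`time_ms`, `lat`, `lon`), one row per
#'   sample; row i is the position after sample i's step.
#' @export
dead_reckon <- function(heading, speed, dt, start, time_ms = NULL,
                        R = EARTH_RADIUS) {
  n <- length(heading)
  stopifnot(length(speed) == n)
  dt <- rep_len(dt, n)
  if (abs(start[1]) >= 90 && any(speed * dt > 0, na.rm = TRUE)) {
    stop("start position is at a pole: longitude undefined")
  }
  q <- speed * dt / R
  lat <- numeric(n); lon <- numeric(n)
  la <- start[1]; lo <- start[2]
  for (i in seq_len(n)) {
    if (!is.na(heading[i]) && !is.na(q[i]) && q[i] != 0) {
      p <- step_destination(la, lo, heading[i], q[i])
      la <- p[1]; lo <- p[2]
    }
    lat[i] <- la; lon[i] <- lo
  }
  if (is.null(time_ms)) time_ms <- rep(NA_real_, n)
  new_geo_track(time_ms, lat, lon, start, R)
}

#' @export
print.geo_track <- function(x, ...) {
  cat("<geo_track> ", nrow(x), " positions, start ",
      paste(signif(attr(x, "start"), 8), collapse = ", "), "\n", sep = "")
  if (nrow(x)) {
    cat("final position: ", signif(x$lat[nrow(x)], 8), ", ",
        signif(x$lon[nrow(x)], 8), "\n", sep = "")
  }
  invisible(x)
}

# integrate one segment from an anchor, returning only the endpoint
integrate_segment <- function(anchor, heading, q) {
  la <- anchor[1]; lo <- anchor[2]
  for (i in seq_along(heading)) {
    if (!is.na(heading[i]) && !is.na(q[i]) && q[i] != 0) {
      p <- step_destination(la, lo, heading[i], q[i])
      la <- p[1]; lo <- p[2]
    }
  }
  c(la, lo)
}

# integrate one segment keeping every position
integrate_segment_full <- function(anchor, heading, q) {
  n <- length(heading)
  lat <- numeric(n); lon <- numeric(n)
  la <- anchor[1]; lo <- anchor[2]
  for (i in seq_len(n)) {
    if (!is.na(heading[i]) && !is.na(q[i]) && q[i] != 0) {
      p <- step_destination(la, lo, heading[i], q[i])
      la <- p[1]; lo <- p[2]
    }
    lat[i] <- la; lon[i] <- lo
  }
  list(lat = lat, lon = lon)
}

#' Correct a dead-reckoned track against ground-truth fixes
#'
#' Between each pair of consecutive fixes the dead-reckoned segment is
#' iteratively adjusted: a constant heading coefficient
#' `hC = gpsHeading - drHeading` is added to every sample heading in the
#' segment and a speed coefficient `sC = gpsDistance / drDistance`
#' multiplies every sample speed, where the `dr` quantities are the bearing
#' and great-circle distance between the segment's current integrated
#' endpoints and the `gps` quantities those between its bounding fixes. The
#' segment is re-integrated and the adjustment repeated until the updates
#' fall below the tolerances or `max_iter` is reached; each accepted
#' iteration tightens the path onto the fixes. Every segment is anchored
#' exactly at its opening fix, resetting the accumulated error; the track
#' start is forced to the first fix. Samples after the last fix reuse the
#' last segment's coefficients (systematic error is assumed to persist);
#' samples before the first fix are translated so the first-fix sample
#' coincides with the fix.
#'
#' @param heading per-sample geographic heading in degrees.
#' @param speed per-sample speed in m/s.
#' @param dt sample interval(s) in seconds.
#' @param time_ms per-sample timestamps (ms), used to locate the fixes.
#' @param fixes a [fix_set] with >= 2 fixes inside the sample span.
#' @param max_iter maximum adjustment iterations per segment.
#' @param heading_tol stop when the heading update |hC step| is below this
#'   (degrees).
#' @param speed_tol stop when the speed update |sC step - 1| is below this
#'   (fraction).
#' @param R earth radius in metres.
#' @return list with `track` (the corrected `geo_track`) and `corrections`,
#'   a data frame per segment: `hC` (degrees), `sC`, `iterations`,
#'   `residual_m` (endpoint miss at the closing fix) and `flagged`
#'   (constant-speed fallback applied because the uncorrected segment did
#'   not move); attribute `residual_history` holds the per-iteration
#'   endpoint residuals of every segment.
#' @export
correct_track <- function(heading, speed, dt, time_ms, fixes,
                          max_iter = 10, heading_tol = 0.1,
                          speed_tol = 0.001, R = EARTH_RADIUS) {
  n <- length(heading)
  stopifnot(length(speed) == n, length(time_ms) == n)
  dt <- rep_len(dt, n)
  if (nrow(fixes) < 2) stop("need at least 2 fixes to correct a track")
  # nearest sample at or after each fix timestamp
  fi <- vapply(fixes$time_ms, function(ft) which.min(abs(time_ms - ft)),
               integer(1))
  if (anyDuplicated(fi)) stop("two fixes map to the same sample")
  if (is.unsorted(fi)) stop("fixes are not ordered along the track")
  q <- speed * dt / R
  lat <- numeric(n); lon <- numeric(n)
  nseg <- nrow(fixes) - 1
  hist <- vector("list", nseg)
  corr <- data.frame(hC = numeric(nseg), sC = numeric(nseg),
                     iterations = integer(nseg), residual_m = numeric(nseg),
                     flagged = logical(nseg))
  for (k in seq_len(nseg)) {
    i0 <- fi[k]; i1 <- fi[k + 1]
    idx <- (i0 + 1):i1
    anchor <- c(fixes$lat[k], fixes$lon[k])
    target <- c(fixes$lat[k + 1], fixes$lon[k + 1])
    gpsD <- fix_distance(anchor[1], anchor[2], target[1], target[2], R)
    gpsH <- if (gpsD > 0) fix_heading(anchor[1], anchor[2], target[1], target[2]) else NA_real_
    hC <- 0; sC <- 1
    seg_h <- heading[idx]; seg_q <- q[idx]
    flagged <- FALSE
    # degenerate: no dead-reckoned movement but the fixes moved
    if (sum(abs(seg_q), na.rm = TRUE) == 0 && gpsD > 0) {
      flagged <- TRUE
      seg_q <- rep(gpsD / R / length(idx), length(idx))
      seg_h <- rep(if (is.na(gpsH)) 0 else gpsH, length(idx))
    }
    res_hist <- numeric(0)
    iter <- 0L
    repeat {
      e <- integrate_segment(anchor, wrap360(seg_h + hC), seg_q * sC)
      res <- fix_distance(e[1], e[2], target[1], target[2], R)
      res_hist <- c(res_hist, res)
      drD <- fix_distance(anchor[1], anchor[2], e[1], e[2], R)
      if (iter >= max_iter || is.na(gpsH)) break
      if (drD == 0) { # cannot recover by scaling: constant-speed fallback
        flagged <- TRUE
        seg_q <- rep(gpsD / R / length(idx), length(idx))
        iter <- iter + 1L
        next
      }
      dH <- wrap180(gpsH - fix_heading(anchor[1], anchor[2], e[1], e[2]))
      ratio <- gpsD / drD
      if (abs(dH) < heading_tol && abs(ratio - 1) < speed_tol) break
      hC <- wrap180(hC + dH)
      sC <- sC * ratio
      iter <- iter + 1L
    }
    full <- integrate_segment_full(anchor, wrap360(seg_h + hC), seg_q * sC)
    lat[idx] <- full$lat; lon[idx] <- full$lon
    lat[i0] <- anchor[1]; lon[i0] <- anchor[2]
    corr$hC[k] <- hC; corr$sC[k] <- sC; corr$iterations[k] <- iter
    corr$residual_m[k] <- res_hist[length(res_hist)]
    corr$flagged[k] <- flagged
    hist[[k]] <- res_hist
    if (flagged) {
      message("segment ", k, ": no dead-reckoned movement between fixes; ",
              "constant-speed fallback applied")
    }
  }
  # before the first fix: original shape translated to end at the first fix
  if (fi[1] > 1) {
    dr0 <- integrate_segment_full(c(fixes$lat[1], fixes$lon[1]), heading[1:fi[1]], q[1:fi[1]])
    shift_lat <- fixes$lat[1] - dr0$lat[fi[1]]
    shift_lon <- fixes$lon[1] - dr0$lon[fi[1]]
    lat[1:(fi[1] - 1)] <- dr0$lat[1:(fi[1] - 1)] + shift_lat
    lon[1:(fi[1] - 1)] <- wrap180(dr0$lon[1:(fi[1] - 1)] + shift_lon)
  }
  # after the last fix: continue with the last segment's coefficients
  if (fi[length(fi)] < n) {
    idx <- (fi[length(fi)] + 1):n
    hC <- corr$hC[nseg]; sC <- corr$sC[nseg]
    tail_full <- integrate_segment_full(
      c(fixes$lat[nrow(fixes)], fixes$lon[nrow(fixes)]),
      wrap360(heading[idx] + hC), q[idx] * sC)
    lat[idx] <- tail_full$lat; lon[idx] <- tail_full$lon
  }
  track <- new_geo_track(time_ms, lat, lon,
                         c(fixes$lat[1], fixes$lon[1]), R)
  attr(track, "fix_index") <- fi
  structure(list(track = track, corrections = corr),
            residual_history = hist, class = "corrected_track")
}

#' @export
print.corrected_track <- function(x, ...) {
  cat("<corrected_track> ", nrow(x$corrections), " segments\n", sep = "")
  print(within(x$corrections, {
    hC <- signif(hC, 4); sC <- signif(sC, 5); residual_m <- signif(residual_m, 4)
  }))
  invisible(x)
}
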