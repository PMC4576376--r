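# Independent oracles and fixture builders used across the test suite.
# These deliberately re-derive results by brute force or via a second,
# unrelated implementation, so they cannot share a bug with the package code
# they check.

# brute-force sliding normalized cross-correlation, single channel
brute_ncc <- function(x, t) {
  L <- length(t)
  tz <- t - mean(t)
  tn <- sqrt(sum(tz^2))
  vapply(seq_len(length(x) - L + 1), function(k) {
    w <- x[k:(k + L - 1)]
    wz <- w - mean(w)
    wn <- sqrt(sum(wz^2))
    if (wn == 0) -1 else sum(wz * tz) / (wn * tn)
  }, numeric(1))
}

# brute-force raw sliding dot product
brute_corr <- function(x, t) {
  L <- length(t)
  vapply(seq_len(length(x) - L + 1), function(k) sum(x[k:(k + L - 1)] * t),
         numeric(1))
}

# explicit rotation matrices (independent of the package's vectorised code)
o_rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
o_ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
o_rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# body-frame reading of a world vector for yaw/pitch/roll in degrees
oracle_body_vector <- function(v_world, yaw, pitch, roll) {
  R <- o_rz(yaw * pi / 180) %*% o_ry(pitch * pi / 180) %*% o_rx(roll * pi / 180)
  drop(t(R) %*% v_world)
}

# world magnetic field consistent with the compass convention H = atan2(my, -mx)
oracle_field <- function(B = 1, inclination_deg = 60) {
  i <- inclination_deg * pi / 180
  B * c(-cos(i), 0, -sin(i))
}

# spherical destination point via geosphere (independent geodesy code),
# on an earth of the package's printed radius
oracle_dest <- function(lat, lon, bearing, dist_m) {
  p <- geosphere::destPoint(c(lon, lat), bearing, dist_m, r = 6.371e6)
  c(lat = p[2], lon = p[1])
}

# write a small delimited sensor file; returns the path
write_fixture_csv <- function(df, sep = ",", path = tempfile(fileext = ".csv")) {
  lines <- c(paste(names(df), collapse = sep),
             apply(as.data.frame(lapply(df, as.character)), 1, paste, collapse = sep))
  writeLines(lines, path)
  path
}

# canonical tiny log: 3 rows at 40 Hz
tiny_log_df <- function() {
  data.frame(day = 0L, h = 0L, m = 0L, s = 0L, ms = c(0L, 25L, 50L),
             ax = c(0, 0.1, -0.1), ay = c(0, 0, 0), az = c(1, 1, 1))
}
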