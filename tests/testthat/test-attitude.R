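# Axis maps, static/dynamic split, pitch/roll, tilt compensation, heading.

test_that("axis maps validate and invert; identity map leaves a table unchanged", {
  expect_error(axis_map(mag = matrix(1, 3, 3)), "signed permutation")
  m_swap <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE)
  map <- axis_map(mag = m_swap)
  sim <- simulate_deployment(sim_scenario(seed = 1, duration_s = 5, rate_hz = 10))
  same <- apply_axis_map(sim$table, axis_map())
  expect_equal(as.data.frame(same), as.data.frame(sim$table))
  # map then inverse restores the input
  there <- apply_axis_map(sim$table, map)
  back <- apply_axis_map(there, invert_axis_map(map))
  expect_equal(as.data.frame(back), as.data.frame(sim$table))
})

test_that("a mounting rotation undone by its axis map reproduces the heading", {
  sim <- simulate_deployment(sim_scenario(seed = 2, duration_s = 20, rate_hz = 10,
                                          distortion = list(A = diag(3), b = c(0, 0, 0))))
  mount <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rotated <- apply_axis_map(sim$table, axis_map(mount = mount))
  restored <- apply_axis_map(rotated, invert_axis_map(axis_map(mount = mount)))
  h0 <- derive_attitude(sim$table, 1, 0)$heading
  h1 <- derive_attitude(restored, 1, 0)$heading
  expect_equal(h1, h0, tolerance = 1e-10)
})

test_that("static split: constants pass through, window 1 is identity, edges truncate", {
  a <- cbind(rep(0, 50), rep(0, 50), rep(1, 50))
  st <- static_acceleration(a, 11)
  expect_equal(st$static, a, ignore_attr = TRUE)
  expect_equal(st$dynamic, a * 0, ignore_attr = TRUE)
  x <- rnorm(30)
  expect_equal(running_mean(x, 1), x)
  # truncated edge: first value is the mean of the first half-window
  expect_equal(running_mean(x, 5)[1], mean(x[1:3]))
  expect_equal(running_mean(x, 5)[30], mean(x[28:30]))
  expect_error(running_mean(x, 4), "odd")
  expect_error(running_mean(x, 31), "exceeds")
})

test_that("moving-average gain on a sine matches the closed-form Dirichlet factor", {
  P <- 20; n <- 400
  x <- sin(2 * pi * seq_len(n) / P)
  for (w in c(5, 9, 13)) {
    g <- sin(w * pi / P) / (w * sin(pi / P))
    sm <- running_mean(x, w)
    interior <- (w + 1):(n - w)
    expect_equal(sm[interior], g * x[interior], tolerance = 1e-10)
  }
  # window equal to a full period cancels the sine (interior samples)
  P2 <- 9
  x2 <- sin(2 * pi * seq_len(n) / P2)
  sm2 <- running_mean(x2, 9)
  expect_lt(max(abs(sm2[10:(n - 10)])), 1e-12)
})

test_that("static + dynamic = raw exactly, with missing values skipped", {
  set.seed(4)
  a <- matrix(rnorm(300), 100, 3)
  a[7, 2] <- NA
  st <- static_acceleration(a, 9)
  # dynamic is defined as the exact residual of the split
  expect_identical(st$dynamic, a - st$static)
  expect_equal(st$static + st$dynamic, a, tolerance = 1e-15)
  # the static estimate around the gap uses the remaining samples
  expect_false(is.na(st$static[6, 2]))
})

test_that("pitch/roll: level, nose-up and rotation-oracle recovery", {
  expect_equal(unlist(pitch_roll(rbind(c(0, 0, 1)))), c(pitch = 0, roll = 0))
  expect_equal(pitch_roll(rbind(c(-1, 0, 0)))$pitch, 90)
  expect_true(all(is.na(pitch_roll(rbind(c(0, 0, 0))))))
  set.seed(5)
  for (i in 1:25) {
    yaw <- runif(1, 0, 360); pitch <- runif(1, -89, 89); roll <- runif(1, -179, 179)
    s <- oracle_body_vector(c(0, 0, 1), yaw, pitch, roll)
    pr <- pitch_roll(rbind(s))
    expect_equal(pr$pitch, pitch, tolerance = 1e-9)
    expect_equal(pr$roll, roll, tolerance = 1e-9)
  }
})

test_that("tilt compensation recovers the level-frame vector and handles gimbal lock", {
  set.seed(6)
  f <- oracle_field(1, 60)
  for (i in 1:25) {
    yaw <- runif(1, 0, 360); pitch <- runif(1, -89, 89); roll <- runif(1, -179, 179)
    m <- oracle_body_vector(f, yaw, pitch, roll)
    lev <- tilt_compensate(rbind(m), data.frame(pitch = pitch, roll = roll))
    # level frame = world field rotated by -yaw only
    expect_equal(drop(lev), drop(t(o_rz(yaw * pi / 180)) %*% f),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # zero attitude leaves the vector untouched; NA attitude nulls the row
  m <- rbind(c(0.3, -0.2, 0.5))
  expect_equal(tilt_compensate(m, data.frame(pitch = 0, roll = 0)), m,
               ignore_attr = TRUE)
  expect_true(all(is.na(tilt_compensate(m, data.frame(pitch = NA_real_, roll = 0)))))
  # pitch 90: finite output by the roll = 0 convention
  s <- rbind(c(-1, 0, 0))
  pr <- pitch_roll(s)
  expect_equal(pr$roll, 0)
  expect_true(all(is.finite(tilt_compensate(rbind(c(0.1, 0.2, 0.3)), pr))))
})

test_that("heading honours the printed ratio, quadrants, declination and scale", {
  expect_equal(heading(rbind(c(-1, 0, 0))), 0)
  expect_equal(heading(rbind(c(0, 1, 0))), 90)
  expect_equal(heading(rbind(c(1, 0, 0))), 180)
  expect_equal(heading(rbind(c(0, -1, 0))), 270)
  # declination shifts every heading by exactly d (mod 360)
  set.seed(7)
  m <- matrix(rnorm(60), 20, 3)
  expect_equal(heading(m, 5), (heading(m, 0) + 5) %% 360)
  # invariant to positive rescaling
  expect_equal(heading(m * 7.3), heading(m))
  # vanishing horizontal component: heading undefined
  expect_true(is.na(heading(rbind(c(0, 0, 1)))))
})

test_that("full attitude pipeline recovers simulated heading exactly (noise-free)", {
  sim <- simulate_deployment(sim_scenario(seed = 8, duration_s = 30, rate_hz = 20))
  fit <- fit_ellipsoid(sensor_matrix(sim$table, "mag"))
  tbl <- apply_calibration(sim$table, fit)
  tbl <- derive_attitude(tbl, 1, 0, mag_channels = c("mag_x_cal", "mag_y_cal", "mag_z_cal"))
  expect_lt(max(abs(ddtag:::wrap180(tbl$heading - sim$truth$heading))), 1e-6)
  expect_lt(max(abs(tbl$pitch - sim$truth$pitch)), 1e-9)
  expect_lt(max(abs(ddtag:::wrap180(tbl$roll - sim$truth$roll))), 1e-9)
})
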