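# Spherical dead-reckoning, bearing/distance and fix-based track correction.

test_that("zero speed leaves the track at the start position", {
  tr <- dead_reckon(runif(50, 0, 360), rep(0, 50), 1, c(12.3, -4.5))
  expect_true(all(tr$lat == 12.3 & tr$lon == -4.5))
})

test_that("111.19 km due north from the equator is one degree of latitude", {
  # R * 1 degree = 6.371e6 * pi/180 = 111.19 km
  d <- 6.371e6 * pi / 180
  tr <- dead_reckon(rep(0, 100), rep(d / 100, 100), 1, c(0, 0))
  expect_equal(tr$lat[100], 1, tolerance = 1e-4)
  expect_equal(tr$lon[100], 0, tolerance = 1e-12)
})

test_that("a random walk matches the independent destination-point oracle per step", {
  set.seed(20)
  n <- 500
  H <- runif(n, 0, 360); s <- runif(n, 0, 3)
  tr <- dead_reckon(H, s, 1, c(47.1, 8.6))
  p <- c(47.1, 8.6)
  for (i in seq_len(n)) {
    p <- oracle_dest(p[1], p[2], H[i], s[i])
    expect_lt(abs(tr$lat[i] - p[1]), 1e-9)
    expect_lt(abs(ddtag:::wrap180(tr$lon[i] - p[2])), 1e-9)
  }
})

test_that("missing heading or speed carries the position forward", {
  H <- c(0, NA, 0, 0); s <- c(1, 1, NA, 1)
  tr <- dead_reckon(H, s, 1, c(0, 0))
  expect_equal(tr$lat[2], tr$lat[1])
  expect_equal(tr$lat[3], tr$lat[2])
  expect_gt(tr$lat[4], tr$lat[3])
})

test_that("dead-reckoning from a pole with motion is rejected", {
  expect_error(dead_reckon(0, 1, 1, c(90, 0)), "pole")
})

test_that("bearing and distance: meridian, equator, antipodes, symmetry", {
  expect_equal(fix_heading(0, 0, 1, 0), 0)
  expect_equal(fix_heading(0, 0, 0, 1), 90)
  expect_error(fix_heading(5, 5, 5, 5), "bearing undefined")
  expect_equal(fix_distance(3, 4, 3, 4), 0)
  expect_equal(fix_distance(0, 0, 0, 180), pi * 6.371e6, tolerance = 1)
  set.seed(21)
  la <- runif(20, -80, 80); lo <- runif(20, -180, 180)
  lb <- runif(20, -80, 80); lq <- runif(20, -180, 180)
  expect_equal(fix_distance(la, lo, lb, lq), fix_distance(lb, lq, la, lo))
  expect_equal(fix_distance(la, lo, lb, lq),
               geosphere::distHaversine(cbind(lo, la), cbind(lq, lb), r = 6.371e6),
               tolerance = 1e-6)
})

test_that("one dead-reckoned step with fix_heading/fix_distance lands on the target", {
  set.seed(22)
  n <- 200
  la0 <- runif(n, -75, 75); lo0 <- runif(n, -180, 180)
  la1 <- la0 + runif(n, -2, 2); lo1 <- lo0 + runif(n, -2, 2)
  H <- fix_heading(la0, lo0, la1, lo1)
  d <- fix_distance(la0, lo0, la1, lo1)
  for (i in seq_len(n)) {
    tr <- dead_reckon(H[i], d[i], 1, c(la0[i], lo0[i]))
    expect_lt(abs(tr$lat[1] - la1[i]), 1e-9)
    expect_lt(abs(ddtag:::wrap180(tr$lon[1] - lo1[i])), 1e-9)
  }
})

biased_scenario <- function() {
  sim <- simulate_deployment(sim_scenario(seed = 7, duration_s = 300, rate_hz = 10,
                                          heading_bias_deg = 10, speed_scale = 0.8,
                                          fix_interval_s = 60))
  list(sim = sim,
       res = correct_track(sim$truth$obs_heading, sim$truth$obs_speed, 1 / 10,
                           sim$truth$time_ms, sim$fixes))
}

test_that("fix correction recovers a planted heading bias and speed scale", {
  sc <- biased_scenario()
  corr <- sc$res$corrections
  expect_true(all(abs(corr$hC - (-10)) < 0.5))
  expect_true(all(abs(corr$sC - 1.25) < 0.01))
  # corrected track hits every fix within a metre
  fi <- attr(sc$res$track, "fix_index")
  miss <- fix_distance(sc$res$track$lat[fi], sc$res$track$lon[fi],
                       sc$sim$fixes$lat, sc$sim$fixes$lon)
  expect_lt(max(miss), 1)
  # and the start is forced to the first fix
  expect_equal(sc$res$track$lat[fi[1]], sc$sim$fixes$lat[1])
})

test_that("fix residuals are non-increasing over correction iterations", {
  sc <- biased_scenario()
  for (h in attr(sc$res, "residual_history")) {
    expect_true(all(diff(h) <= 1e-9))
  }
})

test_that("correction with fixes sampled from the track itself is the identity", {
  sim <- simulate_deployment(sim_scenario(seed = 9, duration_s = 120, rate_hz = 10,
                                          fix_interval_s = 30))
  res <- correct_track(sim$truth$heading, sim$truth$speed, 1 / 10,
                       sim$truth$time_ms, sim$fixes)
  expect_true(all(abs(res$corrections$hC) < 0.2))
  expect_true(all(abs(res$corrections$sC - 1) < 0.002))
  d <- fix_distance(res$track$lat, res$track$lon,
                    sim$truth$track$lat, sim$truth$track$lon)
  expect_lt(max(d), 0.5)
})

test_that("a motionless segment with moving fixes takes the flagged fallback", {
  n <- 40
  tmsv <- seq(0, by = 1000, length.out = n)
  H <- rep(0, n); s <- rep(0, n)
  fx <- fix_set(c(0, 39000), c(0, 0.01), c(0, 0))
  expect_message(res <- correct_track(H, s, 1, tmsv, fx), "fallback")
  expect_true(res$corrections$flagged[1])
  fi <- attr(res$track, "fix_index")
  expect_lt(fix_distance(res$track$lat[fi[2]], res$track$lon[fi[2]], 0.01, 0), 1)
})

test_that("correction requires at least two usable fixes", {
  expect_error(correct_track(rep(0, 10), rep(1, 10), 1, 1:10,
                             fix_set(5, 0, 0)), "at least 2")
})
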