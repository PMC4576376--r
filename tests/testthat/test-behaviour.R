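# Template matching: resampling, normalized cross-correlation, match
# extraction, boosting, accept/reject bookkeeping and the template store.

test_that("templates validate their channels and length", {
  expect_error(dd_template(list(a = 1:5, b = 1:4)), "same length")
  expect_error(dd_template(list(a = 1)), "length must be >= 2")
  tpl <- dd_template(list(a = sin(1:10), b = cos(1:10)), animal = "badger",
                     behaviour = "dig")
  expect_s3_class(tpl, "dd_template")
})

test_that("resampling halves/doubles lengths and is identity for p = q", {
  w <- sin(2 * pi * (1:100) / 20)
  expect_length(resample_waveform(w, 1, 2), 50)
  expect_length(resample_waveform(w, 2, 1), 200)
  expect_identical(resample_waveform(w, 3, 3), w)
  expect_error(resample_waveform(w[1:2], 1, 2), "below 2")
})

test_that("a pure sine resampled 2/1 then 1/2 returns within 1% RMS", {
  w <- sin(2 * pi * (1:100) / 20)
  rt <- resample_waveform(resample_waveform(w, 2, 1), 1, 2)
  expect_lt(sqrt(mean((rt - w)^2)) / sqrt(mean(w^2)), 0.01)
})

test_that("frequency-space similarity equals the brute-force sliding correlation", {
  set.seed(30)
  for (n in c(10, 100, 1000)) {
    x <- rnorm(n)
    L <- max(2, n %/% 10)
    t <- rnorm(L)
    tpl <- dd_template(list(ch = t))
    ser <- data.frame(ch = x)
    # normalized mode against the brute-force NCC
    r_pkg <- sliding_similarity(ser, tpl, normalized = TRUE)
    r_ref <- (brute_ncc(x, t) + 1) / 2 * 100
    expect_lt(max(abs(r_pkg - r_ref)), 1e-10)
    # raw mode against the brute-force dot product
    c_pkg <- sliding_similarity(ser, tpl, normalized = FALSE)
    expect_lt(max(abs(c_pkg - brute_corr(x, t))), 1e-10)
  }
})

test_that("self-match scores 100% and is amplitude/offset invariant", {
  set.seed(31)
  x <- rnorm(400)
  k <- 150; L <- 40
  tpl <- dd_template(list(ch = x[k:(k + L - 1)]))
  sim <- sliding_similarity(data.frame(ch = x), tpl)
  expect_equal(sim[k], 100, tolerance = 1e-9)
  # the same slice scaled and offset in the series still matches exactly
  sim2 <- sliding_similarity(data.frame(ch = x * 3 + 2), tpl)
  expect_equal(sim2[k], 100, tolerance = 1e-9)
  expect_equal(sim2, sim, tolerance = 1e-9)
  # multichannel: mean of per-channel correlations
  tpl2 <- dd_template(list(a = x[k:(k + L - 1)], b = rnorm(L)))
  simab <- sliding_similarity(data.frame(a = x, b = rnorm(400)), tpl2)
  expect_true(all(simab >= 0 & simab <= 100))
})

test_that("zero-variance windows score 0 and missing data yields NA", {
  x <- c(rep(1, 20), rnorm(20))
  tpl <- dd_template(list(ch = sin(1:5)))
  sim <- sliding_similarity(data.frame(ch = x), tpl)
  expect_equal(sim[1], 0)
  x2 <- rnorm(30); x2[10] <- NA
  sim2 <- sliding_similarity(data.frame(ch = x2), tpl)
  expect_true(all(is.na(sim2[6:10])))
  expect_false(anyNA(sim2[11:26]))
  expect_error(sliding_similarity(data.frame(ch = x), dd_template(list(ch = rep(2, 4)))),
               "zero variance")
  expect_error(sliding_similarity(data.frame(zz = x), tpl), "lacks template channel")
})

test_that("match extraction: strict threshold, suppression geometry, sorting", {
  sim <- c(50, 95, 94, 50, 50, 50, 96, 50, 50, 50)
  res <- extract_matches(sim, 90, 3)
  # position 3 overlaps the stronger position 2 and is suppressed
  expect_equal(res$start, c(2, 7))
  expect_equal(res$similarity, c(95, 96))
  # threshold 100 keeps only exact matches
  expect_equal(nrow(extract_matches(c(99.9, 100, 99), 100, 2)), 0)
  # ties break to the earliest start
  res2 <- extract_matches(c(90, 90, 10), 80, 2)
  expect_equal(res2$start, 1)
  # threshold 0: suppression bounds the count by floor(N / L)
  set.seed(32)
  simv <- runif(500, 1, 99)
  res3 <- extract_matches(simv, 0, 25)
  expect_lte(nrow(res3), floor((500 + 24) / 25))
  expect_true(all(diff(res3$start) >= 25))
})

test_that("raising the threshold never increases the match count", {
  set.seed(33)
  simv <- runif(2000) * 100
  counts <- vapply(seq(0, 100, by = 5),
                   function(th) nrow(extract_matches(simv, th, 10)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted-motif benchmark: perfect recall and precision at threshold 80", {
  b <- simulate_motif_benchmark(seed = 42, n = 4000, L = 64, k = 20, snr_db = 6)
  sim <- sliding_similarity(b$series, b$template)
  res <- extract_matches(sim, 80, 64)
  expect_equal(nrow(res), 20)
  offs <- vapply(res$start, function(s) min(abs(s - b$starts)), numeric(1))
  expect_true(all(offs <= 2))
  recall <- mean(vapply(b$starts, function(s) any(abs(res$start - s) <= 2), logical(1)))
  expect_equal(recall, 1)
})

test_that("boosting unions template matches and is idempotent for duplicates", {
  set.seed(34)
  n <- 3000
  x <- rnorm(n)
  mk_motif <- function(f) {
    tt <- seq(0, 1, length.out = 50)
    m <- sin(2 * pi * f * tt) * exp(-((tt - 0.5) / 0.3)^2)
    3 * (m - mean(m))
  }
  m1 <- mk_motif(3); m2 <- mk_motif(7)
  s1 <- c(200, 900, 1700); s2 <- c(500, 1300, 2400)
  for (s in s1) x[s:(s + 49)] <- x[s:(s + 49)] + m1
  for (s in s2) x[s:(s + 49)] <- x[s:(s + 49)] + m2
  ser <- data.frame(ch = x)
  t1 <- dd_template(list(ch = m1)); t2 <- dd_template(list(ch = m2))
  r1 <- extract_matches(sliding_similarity(ser, t1), 80, 50)
  rb <- boost(list(t1, t2), ser, 80)
  # single template via boost equals extract_matches
  rb1 <- boost(list(t1), ser, 80)
  expect_equal(rb1$start, r1$start)
  # both families recovered, never fewer than the best single template
  expect_gte(nrow(rb), nrow(r1))
  hit <- function(starts, true) all(vapply(true, function(s) any(abs(starts - s) <= 2), logical(1)))
  expect_true(hit(rb$start, s1))
  expect_true(hit(rb$start, s2))
  # a duplicate template changes nothing
  rb2 <- boost(list(t1, t1), ser, 80)
  expect_equal(rb2$start, rb1$start)
})

test_that("accept/reject bookkeeping: pending queue, rejection memory, regions", {
  set.seed(35)
  x <- rnorm(500)
  k <- c(100, 300); L <- 30
  tpl <- dd_template(list(ch = x[k[1]:(k[1] + L - 1)]))
  x[k[2]:(k[2] + L - 1)] <- x[k[1]:(k[1] + L - 1)]
  ser <- data.frame(ch = x)
  res <- extract_matches(sliding_similarity(ser, tpl), 99, L)
  expect_equal(res$start, k)
  ls <- add_class(label_set(500), "gait")
  ls <- propose_matches(ls, res, 1L)
  expect_equal(nrow(ls$pending), 2)
  # reject one by region, accept the other
  ls <- accept_reject(ls, accept = ls$pending$id[1],
                      reject_regions = data.frame(start = 295, end = 305))
  expect_equal(nrow(ls$pending), 0)
  expect_equal(nrow(ls$intervals), 1)
  expect_equal(ls$intervals$provenance, "matched")
  expect_equal(nrow(ls$rejected), 1)
  # re-running the search does not resurrect the rejected interval
  ls2 <- propose_matches(ls, res, 1L)
  expect_equal(nrow(ls2$pending), 0)
  # unknown ids error
  expect_error(accept_reject(ls, accept = 99), "unknown pending id")
})

test_that("manual labels union same-class runs, reject cross-class overlap, override rejections", {
  ls <- add_class(add_class(label_set(100), "walk"), "rest")
  ls <- manual_label(ls, 10, 20, 1L)
  ls <- manual_label(ls, 21, 30, 1L)  # adjacent same class -> one interval
  expect_equal(nrow(ls$intervals), 1)
  expect_equal(ls$intervals$end, 30)
  expect_error(manual_label(ls, 25, 40, 2L), "overlapping labels of different classes")
  expect_error(manual_label(ls, 95, 120, 1L), "outside series")
  # manual labelling inside a rejected region is allowed
  ls$rejected <- data.frame(start = 50L, end = 60L)
  ls <- manual_label(ls, 52, 58, 2L)
  expect_true(any(ls$intervals$class_id == 2))
  codes <- behaviour_codes(ls, 100)
  expect_equal(unique(codes[52:58]), 2L)
  expect_equal(unique(codes[10:30]), 1L)
  expect_equal(sum(codes == 0), 100 - 21 - 7)
})

test_that("the template store round-trips and queries by animal and behaviour", {
  dir <- file.path(tempfile(), "store")
  t1 <- dd_template(list(ax = sin(1:30), az = cos(1:30)),
                    animal = "badger", behaviour = "dig")
  t2 <- dd_template(list(ax = rnorm(20)), animal = "badger", behaviour = "walk")
  t3 <- dd_template(list(ax = rnorm(25)), animal = "condor", behaviour = "thermal")
  for (tp in list(t1, t2, t3)) store_template(dir, tp)
  back <- query_store(dir, "badger", "dig")[[1]]
  expect_identical(back$channels, t1$channels)
  expect_identical(back$behaviour, "dig")
  all_badger <- query_store(dir, "badger")
  expect_length(all_badger, 2)
  expect_setequal(vapply(all_badger, `[[`, "", "behaviour"), c("dig", "walk"))
  expect_length(query_store(dir, "unknown-animal"), 0)
  expect_error(query_store(dir, "badger", "fly"), "no stored template")
  # plain-file round trip is lossless
  p <- tempfile(fileext = ".tpl")
  write_template(t1, p)
  expect_identical(read_template(p)$channels, t1$channels)
})
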