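test_that("down-sampling selects the nearest sample at each frame time", {
  r <- raw_recording(rep(2.5, 1000), rep(-1, 1000))
  ds <- downsample_gaze(r, std_geom())
  expect_equal(length(ds$x), 240)
  expect_true(all(ds$x == 2.5))
  # a 1 Hz sinusoid survives nearest-sample selection with < 1% amplitude error
  t <- (0:9999) / 1000
  r2 <- raw_recording(sin(2 * pi * t), cos(2 * pi * t))
  ds2 <- downsample_gaze(r2, std_geom())
  expect_equal(ds2$x, sin(2 * pi * ds2$t), tolerance = 0.01)
  expect_error(downsample_gaze(raw_recording(numeric(0), numeric(0))),
               "empty")
})

test_that("length reconciliation trims 0-2 excess frames and rejects more", {
  stim <- 1:100
  expect_equal(reconcile_lengths(1:100, stim), 1:100)
  expect_equal(reconcile_lengths(1:102, stim), 1:100)
  expect_error(reconcile_lengths(1:103, stim), "3 frames")
  expect_error(reconcile_lengths(1:99, stim), "shorter")
})

test_that("velocity peaks and position plateaus are flagged", {
  # smooth ramp at 10 deg/s: nothing flagged
  x <- seq(0, 1, length.out = 25) * 10 / 240 * 24
  qm <- detect_unreliable(x, seq_along(x) * 0.01)
  expect_false(any(qm$mask))
  # a 5 degree single-frame step is 1200 deg/s: both endpoints flagged
  x2 <- c(seq(0, 1, by = 0.01), seq(6, 7, by = 0.01))
  qm2 <- detect_unreliable(x2, numeric(length(x2)) + seq_along(x2) * 1e-3)
  i <- 101:102
  expect_true(all(qm2$mask[i]))
  expect_true(all(qm2$reason[i] == "velocity_peak"))
  expect_false(any(qm2$mask[-i]))
  # 4 identical samples = 3 zero-velocity steps: plateau under default rule
  x3 <- c(1, 2, 3, 3, 3, 3, 4, 5)
  y3 <- c(1, 2, 3, 3, 3, 3, 4, 5)
  qm3 <- detect_unreliable(x3, y3)
  expect_equal(which(qm3$mask), 3:6)
  expect_true(all(qm3$reason[3:6] == "plateau"))
  # exactly 2 identical samples: not flagged by default, flagged in strict mode
  x4 <- c(1, 2, 2, 3, 4, 5)
  expect_false(any(detect_unreliable(x4, x4)$mask))
  expect_true(any(detect_unreliable(x4, x4, plateau_steps = 1L)$mask))
})

test_that("NaN masking pads 0.05 s (12 samples) each side and clips at edges", {
  n <- 200
  m <- logical(n)
  m[100] <- TRUE
  res <- apply_mask(rnorm(n), rnorm(n), m)
  expect_equal(sum(is.nan(res$x)), 25)  # 1 + 12 + 12
  expect_equal(which(is.nan(res$x)), 88:112)
  expect_equal(res$nan_fraction, 25 / 200)
  # flagged run at the start: padding clipped, no negative indices
  m2 <- logical(n)
  m2[1:3] <- TRUE
  res2 <- apply_mask(rnorm(n), rnorm(n), m2)
  expect_equal(which(is.nan(res2$x)), 1:15)
  # empty mask: no NaNs
  res3 <- apply_mask(rnorm(n), rnorm(n), logical(n))
  expect_equal(res3$nan_fraction, 0)
})

test_that("nan_fraction grows monotonically with the padding width", {
  set.seed(4)
  m <- runif(500) < 0.02
  x <- rnorm(500)
  fr <- vapply(c(0, 0.025, 0.05, 0.1, 0.2),
               function(p) apply_mask(x, x, m, pad_s = p)$nan_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("masking is idempotent: a masked signal gains no new flags", {
  set.seed(9)
  x <- cumsum(rnorm(500, 0, 0.05))
  y <- cumsum(rnorm(500, 0, 0.05))
  x[200] <- x[199] + 6  # artifact spike
  x[300:310] <- x[299]  # hold plateau
  y[300:310] <- y[299]
  qm <- detect_unreliable(x, y)
  res <- apply_mask(x, y, qm)
  qm2 <- detect_unreliable(res$x, res$y)
  res2 <- apply_mask(res$x, res$y, qm2)
  expect_equal(sum(is.nan(res2$x)), sum(is.nan(res$x)))
})

test_that("set-level discard rules follow the smooth/saccadic exclusion logic", {
  mk <- function(mode, nanf, seed)
    raw_pair(rnorm(10), rnorm(10), rnorm(10), rnorm(10), mode = mode,
             nan_fraction = nanf, seed = seed)
  # smooth trajectory discarded -> smooth part excluded
  set1 <- list(mk("smooth", 0.6, 1), mk("saccadic", 0.1, 2),
               mk("saccadic", 0.1, 3), mk("saccadic", 0.1, 4))
  r1 <- apply_discard_rules(set1)
  expect_true(r1$smooth_excluded)
  expect_false(r1$saccadic_excluded)
  expect_equal(length(r1$retained), 3)
  # two of three saccadic discarded -> whole saccadic part excluded
  set2 <- list(mk("smooth", 0.1, 1), mk("saccadic", 0.6, 2),
               mk("saccadic", 0.6, 3), mk("saccadic", 0.1, 4))
  r2 <- apply_discard_rules(set2)
  expect_true(r2$saccadic_excluded)
  expect_equal(length(r2$retained), 1)
  # one of three discarded -> saccadic part retained with 2 trajectories
  set3 <- list(mk("smooth", 0.1, 1), mk("saccadic", 0.6, 2),
               mk("saccadic", 0.1, 3), mk("saccadic", 0.1, 4))
  r3 <- apply_discard_rules(set3)
  expect_false(r3$saccadic_excluded)
  expect_equal(length(r3$retained), 3)
  expect_equal(sum(r3$report$discarded), 1)
})

test_that("healthy-preset recordings survive pre-processing nearly untouched", {
  tr <- generate_smooth_trajectory(seed = 13, duration_s = 10)
  prof <- healthy_profile(rng_seed = 31)  # blink rate 0.1 Hz
  g <- simulate_gaze(tr, prof, "OD")$OD
  p <- preprocess_recording(g, tr)
  expect_lt(p$nan_fraction, 0.1)
  expect_false(p$discarded)
})
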