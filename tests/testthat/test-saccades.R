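test_that("stationary gaze with sensor noise produces no saccade events", {
  set.seed(41)
  r <- raw_recording(rnorm(5000, 0, 0.05), rnorm(5000, 0, 0.05))
  expect_equal(nrow(detect_saccades(r)), 0)
})

test_that("simulated saccades are detected with accurate amplitudes", {
  # single 10 degree saccade via the simulator's raised-cosine kinematics
  tr <- structure(list(mode = "saccadic", t = (0:2399) / 240,
                       x = c(rep(0, 1200), rep(10, 1200)), y = numeric(2400),
                       jumps = data.frame(frame_index = 1201L, from_x = 0,
                                          from_y = 0, to_x = 10, to_y = 0),
                       duration_s = 10, seed = 1L, geom = std_geom()),
                  class = "stimulus_trajectory")
  prof <- oculomotor_profile(pursuit_delay_s = 0, position_noise_sd_deg = 0,
                             hypometric_gain = 1, blink_rate_hz = 0)
  g <- simulate_gaze(tr, prof, "OD")$OD
  ev <- detect_saccades(g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_deg, 10, tolerance = 0.5)
  expect_equal(ev$orientation, "horizontal")
  # two 5 degree saccades 300 ms apart stay separate events
  tr2 <- tr
  tr2$x <- c(rep(0, 1000), rep(5, 72), rep(10, 1328))
  tr2$jumps <- data.frame(frame_index = c(1001L, 1073L),
                          from_x = c(0, 5), from_y = 0,
                          to_x = c(5, 10), to_y = 0)
  g2 <- simulate_gaze(tr2, prof, "OD")$OD
  ev2 <- detect_saccades(g2)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$amplitude_deg, c(5, 5), tolerance = 0.5)
})

test_that("detection recovers nearly all injected saccades at 0.3 deg noise", {
  tr <- generate_saccadic_trajectory(seed = 43)
  prof <- healthy_profile(blink_rate_hz = 0, rng_seed = 47,
                          hypometric_gain = 1, max_saccades_per_jump = 1L)
  g <- simulate_gaze(tr, prof, "OD")$OD
  ev <- detect_saccades(g)
  # injected: one saccade per jump, at jump time + latency
  injected <- data.frame(
    t_ms = (tr$jumps$frame_index - 1) / 240 * 1000 + 150,
    amp = sqrt((tr$jumps$to_x - tr$jumps$from_x)^2 +
                 (tr$jumps$to_y - tr$jumps$from_y)^2))
  injected <- injected[injected$amp >= 2, ]
  rel_err <- vapply(seq_len(nrow(injected)), function(i) {
    d <- abs(ev$start_time_ms - injected$t_ms[i])
    j <- which.min(d)
    if (d[j] > 100) return(NA_real_)
    abs(ev$amplitude_deg[j] - injected$amp[i]) / injected$amp[i]
  }, numeric(1))
  expect_gte(mean(!is.na(rel_err)), 0.95)
  expect_lt(median(rel_err, na.rm = TRUE), 0.1)
})

test_that("ESACC lines parse with unit conversion and robust skipping", {
  g <- std_geom()
  lines <- c(
    "MSG\t100 TRIALID 1",
    "SSACC R  1000",
    "ESACC R  1000 1050 50 760.0 540.0 1160.0 540.0 11.3 300.0",
    "ESACC R  2000 2040 40 . . 900.0 500.0 2.0 150.0",
    "EFIX R   1100 1900 800 960.0 540.0 1200",
    "garbage line",
    "ESACC L  3000 3030 30 900.0",
    "ESACC L  3500 3560 60 960.0 540.0 960.0 140.0 8.1 250.0")
  ev <- parse_esacc(lines, g)
  expect_equal(nrow(ev), 2)
  expect_equal(attr(ev, "n_dropped"), 1)
  expect_equal(attr(ev, "n_malformed"), 1)
  expect_equal(ev$start_time_ms, c(1000, 3500))
  expect_equal(ev$duration_ms, c(50, 60))
  expect_equal(ev$peak_velocity_deg_s, c(300, 250))
  # horizontal saccade through the center: endpoints symmetric in degrees
  expect_equal(ev$start_x_deg[1], -ev$end_x_deg[1], tolerance = 0.05)
  expect_equal(ev$orientation, c("horizontal", "vertical"))
  # upward on screen (decreasing pixel row) is a positive-angle vertical
  expect_gt(ev$end_y_deg[2], ev$start_y_deg[2])
  # amplitude recomputed from endpoints by default, parsed on request
  ev2 <- parse_esacc(lines, g, trust_amplitude = TRUE)
  expect_equal(ev2$amplitude_deg, c(11.3, 8.1))
  expect_warning(out <- parse_esacc(c("MSG 1", "EFIX R 1 2 3"), g),
                 "no ESACC")
  expect_equal(nrow(out), 0)
})

test_that("the bundled synthetic ASCII excerpt parses and filters cleanly", {
  f <- system.file("extdata", "synthetic_esacc_sample.asc",
                   package = "sondar")
  ev <- parse_esacc(readLines(f))
  expect_equal(nrow(ev), 12)
  expect_equal(attr(ev, "n_dropped"), 1)
  res <- filter_saccades(ev)
  expect_true(nrow(res$retained) >= 1)
  expect_true(all(res$retained$amplitude_deg >= 2 &
                    res$retained$amplitude_deg <= 50))
})

test_that("the six filter rules remove events in order, boundaries inclusive", {
  mk <- function(amp, dur, vel, ex = amp) {
    data.frame(eye = "R", start_time_ms = 0, end_time_ms = dur,
               duration_ms = dur, start_x_deg = 0, start_y_deg = 0,
               end_x_deg = ex, end_y_deg = 0, amplitude_deg = amp,
               peak_velocity_deg_s = vel, angle_deg = 0,
               orientation = "horizontal", stringsAsFactors = FALSE)
  }
  toy <- rbind(mk(1.5, 50, 300), mk(55, 50, 300), mk(10, 8, 300),
               mk(10, 160, 300), mk(10, 50, 800), mk(10, 50, 300, ex = 30),
               mk(10, 50, 300), mk(10, 50, 300))
  res <- filter_saccades(toy, std_geom())
  expect_equal(nrow(res$retained), 2)
  expect_equal(unname(res$report[c("amp_gt_50", "amp_lt_2", "dur_lt_10",
                                   "dur_gt_150", "vel_gt_750",
                                   "off_screen")]),
               rep(1L, 6))
  # boundary values are retained (rules are strict inequalities)
  edge <- rbind(mk(2, 10, 750), mk(50, 150, 750, ex = 20))
  expect_equal(nrow(filter_saccades(edge, std_geom())$retained), 2)
  # empty input
  e <- filter_saccades(toy[0, ], std_geom())
  expect_equal(nrow(e$retained), 0)
  expect_equal(unname(e$report["retained"]), 0L)
  # filtering is idempotent and order-preserving
  again <- filter_saccades(res$retained, std_geom())
  expect_identical(again$retained, res$retained)
})

test_that("orientation classification partitions the circle", {
  expect_equal(classify_orientation(90), "vertical")
  expect_equal(classify_orientation(0), "horizontal")
  expect_equal(classify_orientation(45), "vertical")    # half-open lower bound
  expect_equal(classify_orientation(135), "horizontal")
  expect_equal(classify_orientation(225), "vertical")
  expect_equal(classify_orientation(315), "horizontal")
  angles <- seq(0, 359.5, by = 0.5)
  cls <- classify_orientation(angles)
  expect_true(all(cls %in% c("horizontal", "vertical")))
  expect_identical(classify_orientation(angles + 360), cls)
  expect_equal(sum(cls == "vertical"), sum(cls == "horizontal"))
  expect_error(classify_orientation(NA_real_), "NA")
})

test_that("amplitude summaries give per-participant, per-orientation medians", {
  ev <- data.frame(participant = rep(c("a", "b"), each = 3),
                   orientation = "horizontal",
                   amplitude_deg = c(3, 4, 5, 7, 8, 20))
  s <- amplitude_summary(ev)
  expect_equal(s$median_amplitude_deg[s$participant == "a"], 4)
  expect_equal(s$median_amplitude_deg[s$participant == "b"], 8)
  expect_equal(s$n_saccades, c(3L, 3L))
  single <- amplitude_summary(data.frame(participant = "a",
                                         orientation = "vertical",
                                         amplitude_deg = 6.2))
  expect_equal(single$median_amplitude_deg, 6.2)
  expect_s3_class(amplitude_summary(ev[0, ]), "excluded_outcome")
})

test_that("hypometric tracking lowers the median saccade amplitude", {
  tr <- generate_saccadic_trajectory(seed = 44)
  healthy <- filter_saccades(detect_saccades(
    simulate_gaze(tr, healthy_profile(blink_rate_hz = 0, rng_seed = 3),
                  "OD")$OD))$retained
  case <- filter_saccades(detect_saccades(
    simulate_gaze(tr, case_profile(blink_rate_hz = 0, rng_seed = 3),
                  "OD")$OD))$retained
  expect_lt(median(case$amplitude_deg), median(healthy$amplitude_deg))
})

test_that("the main-sequence table centers amplitude and keeps every event", {
  ev <- data.frame(participant = rep(c("a", "b"), each = 5),
                   orientation = "horizontal",
                   amplitude_deg = runif(10, 2, 20),
                   peak_velocity_deg_s = runif(10, 100, 400))
  meta <- data.frame(participant = c("a", "b"), group = c("control", "case"),
                     viewing = "binocular", age = c(60, 65),
                     bcva = c(0, 0.1))
  tab <- main_sequence_table(ev, meta)
  expect_equal(nrow(tab), 10)
  expect_equal(mean(tab$amplitude_centered), 0)
  expect_true(all(tab$complete))
  meta2 <- meta
  meta2$age[2] <- NA
  tab2 <- main_sequence_table(ev, meta2)
  expect_equal(sum(!tab2$complete), 5)
})
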