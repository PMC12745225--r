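#' Oculomotor profile for the gaze simulator
#'
#' Parameter set describing a simulated tracker. The pursuit pathway follows
#' the smooth component of the stimulus with a latency (`pursuit_delay_s`)
#' and a gain; the saccadic pathway responds to stimulus jumps after
#' `saccade_latency_s` with one or more saccades, each covering
#' `hypometric_gain` of the remaining position error (1 = a single accurate
#' saccade; values well below 1 produce the multi-step hypometric pattern
#' seen in cerebellar disease). Saccade peak velocity is linear in amplitude
#' (the main sequence): `v = velocity_at_mean_amp + slope * (A - mean_amplitude)`.
#' In binocular simulation the left-eye trace equals the right-eye generative
#' trace minus `disconjugacy_offset_deg` (OD - OS convention) plus
#' independent noise. Blinks are Poisson events during which the recorded
#' position repeats the last tracked value, mimicking the acquisition
#' artifact that pre-processing must detect.
#'
#' @param pursuit_delay_s Pursuit latency in seconds.
#' @param pursuit_gain Pursuit gain in (0, 1].
#' @param position_noise_sd_deg SD of positional noise, degrees. The noise
#'   is band-limited (white noise smoothed over `noise_smooth_s`), mimicking
#'   the low-frequency drift/tremor character of real gaze noise rather
#'   than broadband sensor noise.
#' @param noise_smooth_s Smoothing window of the positional noise, s
#'   (default 0.2, concentrating the noise power below a few Hz as in real
#'   fixational drift).
#' @param saccade_latency_s Latency before each saccade in a response, s.
#' @param main_sequence_slope_deg_per_s_per_deg Main-sequence slope.
#' @param main_sequence_velocity_at_mean_amp Peak velocity (deg/s) at
#'   `mean_amplitude_deg`.
#' @param mean_amplitude_deg Amplitude at which the main-sequence line is
#'   anchored (default 6.5 deg).
#' @param hypometric_gain Fraction of remaining error covered per saccade.
#' @param max_saccades_per_jump Cap on saccades per stimulus jump.
#' @param disconjugacy_offset_deg Length-2 vector, horizontal and vertical
#'   OD - OS positional offset in degrees.
#' @param blink_rate_hz Blink rate (Poisson), Hz.
#' @param blink_duration_s Blink duration, s.
#' @param rng_seed Integer seed for the simulator noise streams.
#' @return An object of class `oculomotor_profile`.
#' @seealso [healthy_profile()], [case_profile()], [simulate_gaze()]
#' @export
oculomotor_profile <- function(pursuit_delay_s = 0.15,
                               pursuit_gain = 1,
                               position_noise_sd_deg = 0.3,
                               noise_smooth_s = 0.2,
                               saccade_latency_s = 0.15,
                               main_sequence_slope_deg_per_s_per_deg = 14.2,
                               main_sequence_velocity_at_mean_amp = 237,
                               mean_amplitude_deg = 6.5,
                               hypometric_gain = 0.9,
                               max_saccades_per_jump = 2L,
                               disconjugacy_offset_deg = c(0, 0),
                               blink_rate_hz = 0,
                               blink_duration_s = 0.15,
                               rng_seed = 1L) {
  stopifnot(pursuit_gain > 0, pursuit_gain <= 1,
            hypometric_gain > 0, hypometric_gain <= 1,
            pursuit_delay_s >= 0, saccade_latency_s >= 0,
            main_sequence_slope_deg_per_s_per_deg > 0,
            blink_rate_hz >= 0, blink_duration_s >= 0,
            length(disconjugacy_offset_deg) == 2)
  structure(list(
    pursuit_delay_s = pursuit_delay_s,
    pursuit_gain = pursuit_gain,
    position_noise_sd_deg = position_noise_sd_deg,
    noise_smooth_s = noise_smooth_s,
    saccade_latency_s = saccade_latency_s,
    main_sequence_slope_deg_per_s_per_deg = main_sequence_slope_deg_per_s_per_deg,
    main_sequence_velocity_at_mean_amp = main_sequence_velocity_at_mean_amp,
    mean_amplitude_deg = mean_amplitude_deg,
    hypometric_gain = hypometric_gain,
    max_saccades_per_jump = as.integer(max_saccades_per_jump),
    disconjugacy_offset_deg = disconjugacy_offset_deg,
    blink_rate_hz = blink_rate_hz,
    blink_duration_s = blink_duration_s,
    rng_seed = as.integer(rng_seed)),
    class = "oculomotor_profile")
}

#' Healthy-tracker simulation preset
#'
#' Low-noise, accurate tracking: pursuit delay 0.15 s, gain 1, positional
#' noise SD 0.3 deg, saccade latency 0.15 s, near-complete saccades
#' (hypometric gain 0.9, at most 2 saccades per jump), no disconjugacy,
#' occasional blinks (0.1 Hz).
#'
#' @param ... Overrides passed to [oculomotor_profile()].
#' @export
healthy_profile <- function(...) {
  args <- utils::modifyList(list(blink_rate_hz = 0.1), list(...))
  do.call(oculomotor_profile, args)
}

#' Ataxia-like simulation preset
#'
#' Hypometric multi-step saccades (gain 0.4, up to 5 saccades per jump), a
#' 1.4 deg horizontal disconjugacy between the eyes, and a steeper main
#' sequence; pursuit otherwise as in [healthy_profile()].
#'
#' @param ... Overrides passed to [oculomotor_profile()].
#' @export
case_profile <- function(...) {
  args <- utils::modifyList(
    list(hypometric_gain = 0.4, max_saccades_per_jump = 5L,
         disconjugacy_offset_deg = c(1.4, 0),
         main_sequence_slope_deg_per_s_per_deg = 18.6,
         blink_rate_hz = 0.1),
    list(...))
  do.call(oculomotor_profile, args)
}

#' @export
print.oculomotor_profile <- function(x, ...) {
  cat("Oculomotor profile:\n")
  cat(sprintf("  pursuit: delay %g s, gain %g, noise SD %g deg\n",
              x$pursuit_delay_s, x$pursuit_gain, x$position_noise_sd_deg))
  cat(sprintf("  saccades: latency %g s, hypometric gain %g, max %d/jump\n",
              x$saccade_latency_s, x$hypometric_gain, x$max_saccades_per_jump))
  cat(sprintf("  main sequence: %g deg/s/deg, %g deg/s at %g deg\n",
              x$main_sequence_slope_deg_per_s_per_deg,
              x$main_sequence_velocity_at_mean_amp, x$mean_amplitude_deg))
  cat(sprintf("  disconjugacy (OD-OS): (%g, %g) deg; blinks %g Hz x %g s\n",
              x$disconjugacy_offset_deg[1], x$disconjugacy_offset_deg[2],
              x$blink_rate_hz, x$blink_duration_s))
  invisible(x)
}

# White noise smoothed with a moving average, rescaled to the target SD.
band_limited_noise <- function(n, sd, smooth_s, fs) {
  if (sd == 0) return(numeric(n))
  w <- max(1L, round(smooth_s * fs))
  z <- stats::rnorm(n + w - 1)
  s <- as.numeric(stats::filter(z, rep(1 / w, w), sides = 1))
  s <- s[w:(n + w - 1)]
  s * sd * sqrt(w)
}

# Raised-cosine position ramp: 0 before onset, 1 after completion.
# u = (t - t0) / duration; w(u) = u - sin(2*pi*u)/(2*pi) on [0, 1].
raised_cosine_ramp <- function(t, t0, duration) {
  u <- (t - t0) / duration
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

main_sequence_velocity <- function(amp, profile) {
  pmax(profile$main_sequence_velocity_at_mean_amp +
         profile$main_sequence_slope_deg_per_s_per_deg *
         (amp - profile$mean_amplitude_deg), 50)
}

# Cumulative saccadic response (n x 2 matrix) to one stimulus jump of
# displacement `d` occurring at time tj. Each saccade covers
# hypometric_gain of the remaining error; below 1 deg of remaining error
# (or past the saccade cap) the residual is absorbed by pursuit, modelled
# as an exponential relaxation.
jump_response <- function(t, tj, d, profile) {
  out <- matrix(0, length(t), 2)
  remaining <- d
  t_cursor <- tj
  n_sacc <- 0L
  while (sqrt(sum(remaining^2)) > 1 && n_sacc < profile$max_saccades_per_jump) {
    t_cursor <- t_cursor + profile$saccade_latency_s
    step <- profile$hypometric_gain * remaining
    amp <- sqrt(sum(step^2))
    dur <- 2 * amp / main_sequence_velocity(amp, profile)
    ramp <- raised_cosine_ramp(t, t_cursor, dur)
    out[, 1] <- out[, 1] + step[1] * ramp
    out[, 2] <- out[, 2] + step[2] * ramp
    remaining <- remaining - step
    t_cursor <- t_cursor + dur
    n_sacc <- n_sacc + 1L
  }
  if (sqrt(sum(remaining^2)) > 0) {
    tau <- 0.3
    relax <- ifelse(t > t_cursor, 1 - exp(-(t - t_cursor) / tau), 0)
    out[, 1] <- out[, 1] + remaining[1] * relax
    out[, 2] <- out[, 2] + remaining[2] * relax
  }
  out
}

#' Simulate gaze recordings for a stimulus trajectory
#'
#' Generates per-eye gaze at 1000 Hz. The deterministic trace is the sum of
#' a pursuit component (the smooth stimulus component, delayed by the
#' pursuit latency and scaled by the gain) and a saccadic component that
#' responds to each stimulus jump with a latency-delayed sequence of
#' raised-cosine saccades obeying the profile's main sequence. White
#' positional noise is added per eye; in binocular mode the OS trace is the
#' generative trace minus the profile's OD-OS disconjugacy offset plus
#' independent noise. During blinks `tracked` is FALSE and the recorded
#' position repeats the last tracked value bit-identically.
#'
#' Deterministic given the trajectory and the profile's `rng_seed`.
#'
#' @param trajectory A `stimulus_trajectory`.
#' @param profile An `oculomotor_profile`.
#' @param eyes Character vector, subset of `c("OD", "OS")`.
#' @param participant_id Identifier stored in the recording.
#' @param fs Gaze sampling rate in Hz (default 1000, the eye-tracker native
#'   rate).
#' @return A list of `gaze_recording` objects, one per requested eye.
#' @export
simulate_gaze <- function(trajectory, profile, eyes = c("OD", "OS"),
                          participant_id = "sim", fs = 1000) {
  stopifnot(inherits(trajectory, "stimulus_trajectory"),
            inherits(profile, "oculomotor_profile"),
            all(eyes %in% c("OD", "OS")), length(eyes) >= 1)
  eyes <- unique(eyes)
  viewing <- if (length(eyes) == 2) "binocular" else "monocular"
  n <- round(trajectory$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # split the stimulus into its smooth component and cumulative jump steps
  sx <- trajectory$x
  sy <- trajectory$y
  if (nrow(trajectory$jumps) > 0) {
    for (k in seq_len(nrow(trajectory$jumps))) {
      j <- trajectory$jumps[k, ]
      idx <- j$frame_index:length(sx)
      sx[idx] <- sx[idx] - (j$to_x - j$from_x)
      sy[idx] <- sy[idx] - (j$to_y - j$from_y)
    }
  }
  # pursuit: delayed, gain-scaled smooth component, resampled to fs
  td <- t - profile$pursuit_delay_s
  gx <- profile$pursuit_gain *
    stats::approx(trajectory$t, sx, xout = td, rule = 2)$y
  gy <- profile$pursuit_gain *
    stats::approx(trajectory$t, sy, xout = td, rule = 2)$y
  # saccadic responses to each jump (targets include the pursuit gain)
  if (nrow(trajectory$jumps) > 0) {
    for (k in seq_len(nrow(trajectory$jumps))) {
      j <- trajectory$jumps[k, ]
      tj <- trajectory$t[j$frame_index]
      d <- profile$pursuit_gain * c(j$to_x - j$from_x, j$to_y - j$from_y)
      r <- jump_response(t, tj, d, profile)
      gx <- gx + r[, 1]
      gy <- gy + r[, 2]
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((as.numeric(profile$rng_seed) * 7919 +
              as.numeric(trajectory$seed) %% 7919) %% 2147483647)
  out <- lapply(eyes, function(eye) {
    ex <- gx
    ey <- gy
    if (eye == "OS") {
      ex <- ex - profile$disconjugacy_offset_deg[1]
      ey <- ey - profile$disconjugacy_offset_deg[2]
    }
    ex <- ex + band_limited_noise(n, profile$position_noise_sd_deg,
                                  profile$noise_smooth_s, fs)
    ey <- ey + band_limited_noise(n, profile$position_noise_sd_deg,
                                  profile$noise_smooth_s, fs)
    tracked <- rep(TRUE, n)
    if (profile$blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, profile$blink_rate_hz * trajectory$duration_s)
      if (n_blinks > 0) {
        onsets <- sort(stats::runif(n_blinks, 0, trajectory$duration_s))
        for (b in onsets) {
          idx <- which(t >= b & t < b + profile$blink_duration_s)
          idx <- idx[idx > 1]
          if (length(idx) > 0) {
            tracked[idx] <- FALSE
            hold <- idx[1] - 1L
            ex[idx] <- ex[hold]
            ey[idx] <- ey[hold]
          }
        }
      }
    }
    structure(list(participant_id = participant_id, eye = eye,
                   viewing = viewing, t = t, x = ex, y = ey,
                   tracked = tracked, fs = fs,
                   mode = trajectory$mode,
                   trajectory_seed = trajectory$seed),
              class = "gaze_recording")
  })
  names(out) <- eyes
  out
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "Gaze recording: %s %s (%s viewing), %s pursuit, %d samples @ %g Hz, %.1f%% tracked\n",
    x$participant_id, x$eye, x$viewing, x$mode, length(x$t), x$fs,
    100 * mean(x$tracked)))
  invisible(x)
}
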