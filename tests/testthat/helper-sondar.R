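# Shared fixtures, all built in code.

std_geom <- function() display_geometry(24.5, c(1920L, 1080L), 240, 60)

# A gaze_recording built directly from vectors (for detector/unit tests).
raw_recording <- function(x, y, fs = 1000, tracked = rep(TRUE, length(x)),
                          eye = "OD", viewing = "monocular",
                          mode = "saccadic") {
  structure(list(participant_id = "test", eye = eye, viewing = viewing,
                 t = (seq_along(x) - 1) / fs, x = x, y = y,
                 tracked = tracked, fs = fs, mode = mode,
                 trajectory_seed = 1L),
            class = "gaze_recording")
}

# A clean_pair built directly from vectors (for outcome-level tests).
raw_pair <- function(stim_x, stim_y, gaze_x, gaze_y, mode = "smooth",
                     eye = "OD", viewing = "binocular", seed = 1L,
                     nan_fraction = 0, participant = "test") {
  structure(list(stim_x = stim_x, stim_y = stim_y,
                 gaze_x = gaze_x, gaze_y = gaze_y,
                 t = (seq_along(stim_x) - 1) / 240,
                 nan_fraction = nan_fraction,
                 discarded = nan_fraction > 0.5,
                 mode = mode, eye = eye, trajectory_seed = seed,
                 participant_id = participant, viewing = viewing, fs = 240),
            class = "clean_pair")
}

# A csf object built directly from a value grid (for the peak rule).
raw_csf <- function(delay_s, value, fs = 240) {
  structure(list(delay_s = delay_s, value = value, fs = fs),
            class = "sonda_csf")
}

# Independent Benjamini-Hochberg step-up, written from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}
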