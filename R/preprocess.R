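# Pre-processing: time-link gaze to the stimulus frame base, reconcile
# vector lengths, flag unreliable signal periods, NaN-mask with padding,
# and apply the trajectory/set discard rules.

#' Down-sample gaze to the stimulus frame rate
#'
#' Selects, for each stimulus frame time, the nearest gaze sample
#' (no anti-alias filtering, preserving saccade edges). Untracked samples
#' and NaNs propagate.
#'
#' @param recording A `gaze_recording` at its native rate (1000 Hz).
#' @param geom A `display_geometry`; its refresh rate (240 Hz) sets the
#'   target frame base.
#' @param n_frames Number of output frames; defaults to the full duration.
#' @return A `gaze_recording` resampled to the frame base (fields `t`, `x`,
#'   `y`, `tracked` at `geom$refresh_hz`).
#' @export
downsample_gaze <- function(recording, geom = display_geometry(),
                            n_frames = NULL) {
  stopifnot(inherits(recording, "gaze_recording"))
  if (length(recording$t) == 0) stop("empty recording")
  fps <- geom$refresh_hz
  if (is.null(n_frames))
    n_frames <- floor(length(recording$t) / recording$fs * fps)
  ft <- (seq_len(n_frames) - 1) / fps
  idx <- pmin(round(ft * recording$fs) + 1L, length(recording$t))
  out <- recording
  out$t <- ft
  out$x <- recording$x[idx]
  out$y <- recording$y[idx]
  out$tracked <- recording$tracked[idx]
  out$fs <- fps
  out
}

#' Reconcile gaze and stimulus vector lengths
#'
#' Recording timing slop leaves the gaze vector 0-2 frames longer than the
#' stimulus vector; the gaze samples from the start up to the stimulus
#' length are kept. A discrepancy outside 0-2 frames is an error.
#'
#' @param gaze_vec Gaze position vector (one axis) at the frame rate.
#' @param stim_vec Stimulus position vector of the target length.
#' @param max_excess Largest tolerated excess, frames (default 2).
#' @return `gaze_vec` trimmed to `length(stim_vec)`.
#' @export
reconcile_lengths <- function(gaze_vec, stim_vec, max_excess = 2L) {
  excess <- length(gaze_vec) - length(stim_vec)
  if (excess < 0)
    stop("reconciliation error: gaze vector shorter than stimulus vector")
  if (excess > max_excess)
    stop(sprintf("reconciliation error: gaze exceeds stimulus by %d frames (max %d)",
                 excess, max_excess))
  gaze_vec[seq_along(stim_vec)]
}

#' Detect unreliable signal periods
#'
#' Flags (1) unrealistic velocity peaks: 2-D point-to-point speed above
#' `vel_limit` (750 deg/s), with both endpoints of a flagged step marked;
#' and (2) position plateaus: zero velocity for at least `plateau_steps`
#' consecutive inter-sample steps (exact positional repeats, the signature
#' of blink hold-fill). With the default `plateau_steps = 2` a run of at
#' least 3 identical samples is flagged; `plateau_steps = 1` gives the
#' strict two-identical-samples reading. `per_axis = TRUE` applies the
#' velocity test per axis instead of to the 2-D displacement.
#'
#' @param x,y Gaze positions in degrees at the frame rate.
#' @param fs Sampling rate, Hz (default 240).
#' @param vel_limit Velocity limit, deg/s (default 750).
#' @param plateau_steps Minimum run of zero-velocity steps (default 2).
#' @param per_axis Velocity test per axis? (default FALSE, 2-D).
#' @return Object of class `quality_mask`: list with logical `mask` and
#'   character `reason` ("", "velocity_peak", "plateau") per sample.
#' @export
detect_unreliable <- function(x, y, fs = 240, vel_limit = 750,
                              plateau_steps = 2L, per_axis = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n)
  mask <- logical(n)
  reason <- character(n)
  if (n >= 2) {
    dx <- diff(x)
    dy <- diff(y)
    fast <- if (per_axis) {
      (abs(dx) * fs > vel_limit) | (abs(dy) * fs > vel_limit)
    } else {
      sqrt(dx^2 + dy^2) * fs > vel_limit
    }
    fast[is.na(fast)] <- FALSE
    hit <- which(fast)
    mask[hit] <- TRUE
    mask[hit + 1L] <- TRUE
    reason[mask] <- "velocity_peak"

    zero <- (dx == 0) & (dy == 0)
    zero[is.na(zero)] <- FALSE
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= plateau_steps)) {
      idx <- starts[j]:(ends[j] + 1L)  # steps i..k involve samples i..k+1
      mask[idx] <- TRUE
      reason[idx] <- ifelse(reason[idx] == "velocity_peak",
                            reason[idx], "plateau")
    }
  }
  structure(list(mask = mask, reason = reason, fs = fs),
            class = "quality_mask")
}

#' NaN-mask unreliable periods with padding
#'
#' Sets each flagged run to NaN, extended by `pad_s` (0.05 s, i.e. 12
#' samples at 240 Hz) on each side, clipped at the vector ends.
#'
#' @param x,y Gaze positions at the frame rate.
#' @param mask A `quality_mask` from [detect_unreliable()], or a logical
#'   vector.
#' @param fs Sampling rate, Hz (default 240).
#' @param pad_s Padding in seconds on each side of a flagged run.
#' @return List with NaN-masked `x`, `y`, and `nan_fraction`.
#' @export
apply_mask <- function(x, y, mask, fs = 240, pad_s = 0.05) {
  m <- if (inherits(mask, "quality_mask")) mask$mask else as.logical(mask)
  stopifnot(length(m) == length(x), length(x) == length(y))
  pad <- round(pad_s * fs)
  if (any(m) && pad > 0) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      lo <- max(1L, starts[j] - pad)
      hi <- min(length(m), ends[j] + pad)
      m[lo:hi] <- TRUE
    }
  }
  x[m] <- NaN
  y[m] <- NaN
  list(x = x, y = y, nan_fraction = mean(m))
}

#' Pre-process one gaze recording against its stimulus trajectory
#'
#' Runs the full chain: down-sample to the frame base, reconcile lengths,
#' detect unreliable periods, NaN-mask with padding, and evaluate the
#' single-trajectory discard rule (more than `discard_fraction` NaN).
#'
#' @param recording A `gaze_recording` (native rate).
#' @param trajectory The linked `stimulus_trajectory`.
#' @param geom A `display_geometry`.
#' @param vel_limit,plateau_steps,per_axis,pad_s,discard_fraction
#'   Pre-processing thresholds; defaults are the standard values
#'   (750 deg/s, 2 steps, 2-D velocity, 0.05 s, 0.5).
#' @return Object of class `clean_pair`: stimulus and masked gaze at the
#'   frame rate, `nan_fraction`, `discarded` flag, `mode`, `eye`,
#'   `participant_id`, `viewing`.
#' @export
preprocess_recording <- function(recording, trajectory,
                                 geom = display_geometry(),
                                 vel_limit = 750, plateau_steps = 2L,
                                 per_axis = FALSE, pad_s = 0.05,
                                 discard_fraction = 0.5) {
  ds <- downsample_gaze(recording, geom)
  gx <- reconcile_lengths(ds$x, trajectory$x)
  gy <- reconcile_lengths(ds$y, trajectory$y)
  qm <- detect_unreliable(gx, gy, fs = geom$refresh_hz,
                          vel_limit = vel_limit,
                          plateau_steps = plateau_steps, per_axis = per_axis)
  masked <- apply_mask(gx, gy, qm, fs = geom$refresh_hz, pad_s = pad_s)
  structure(list(
    stim_x = trajectory$x, stim_y = trajectory$y,
    gaze_x = masked$x, gaze_y = masked$y,
    t = trajectory$t,
    nan_fraction = masked$nan_fraction,
    discarded = masked$nan_fraction > discard_fraction,
    mode = trajectory$mode, eye = recording$eye,
    trajectory_seed = trajectory$seed,
    participant_id = recording$participant_id,
    viewing = recording$viewing, fs = geom$refresh_hz),
    class = "clean_pair")
}

#' @export
print.clean_pair <- function(x, ...) {
  cat(sprintf(
    "Clean pair: %s %s, %s pursuit, %d frames, %.1f%% NaN%s\n",
    x$participant_id, x$eye, x$mode, length(x$t), 100 * x$nan_fraction,
    if (x$discarded) " [DISCARDED]" else ""))
  invisible(x)
}

#' Apply the set-level discard rules
#'
#' A trajectory is discarded when more than half of it is NaN. The smooth
#' pursuit part of a set is excluded when its single trajectory is
#' discarded; the saccadic part is excluded when two or more of its three
#' trajectories are discarded.
#'
#' @param pairs List of `clean_pair` objects for one participant-condition
#'   (1 smooth + up to 3 saccadic).
#' @return List with `retained` (list of clean pairs), `smooth_excluded`,
#'   `saccadic_excluded`, and a `report` data frame of per-trajectory
#'   decisions.
#' @export
apply_discard_rules <- function(pairs) {
  modes <- vapply(pairs, function(p) p$mode, "")
  discarded <- vapply(pairs, function(p) p$discarded, TRUE)
  nanf <- vapply(pairs, function(p) p$nan_fraction, 0)
  smooth_idx <- which(modes == "smooth")
  sacc_idx <- which(modes == "saccadic")
  stopifnot(length(smooth_idx) <= 1, length(sacc_idx) <= 3)
  smooth_excluded <- length(smooth_idx) == 1 && discarded[smooth_idx]
  saccadic_excluded <- sum(discarded[sacc_idx]) >= 2
  keep <- !discarded
  if (smooth_excluded) keep[smooth_idx] <- FALSE
  if (saccadic_excluded) keep[sacc_idx] <- FALSE
  report <- data.frame(
    index = seq_along(pairs), mode = modes, nan_fraction = nanf,
    discarded = discarded,
    part_excluded = (modes == "smooth" & smooth_excluded) |
      (modes == "saccadic" & saccadic_excluded))
  list(retained = pairs[keep],
       smooth_excluded = smooth_excluded,
       saccadic_excluded = saccadic_excluded,
       report = report)
}
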