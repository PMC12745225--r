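# Saccade dynamics: detection on 1000 Hz gaze, EyeLink-ASCII ESACC
# parsing, the six filter rules, orientation classification, amplitude
# summaries and the main-sequence analysis table.

# Savitzky-Golay quadratic first derivative over an odd window (unit
# spacing): coefficients k / sum(k^2), scaled by the sampling rate.
sg_derivative <- function(x, fs, window = 21L) {
  n <- length(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window) return(rep(NA_real_, n))
  h <- (window - 1L) %/% 2L
  k <- seq.int(-h, h)
  d <- stats::filter(x, rev(k / sum(k^2)), sides = 2)
  d <- as.numeric(d) * fs
  # one-sided fill at the edges
  d[seq_len(h)] <- d[h + 1L]
  d[(n - h + 1L):n] <- d[n - h]
  d
}

#' Detect saccades in a gaze recording
#'
#' Velocity/acceleration threshold parser: an event opens when the smoothed
#' 2-D velocity exceeds `vel_thresh` (30 deg/s) or the absolute
#' acceleration exceeds `acc_thresh` (8000 deg/s^2), and closes when both
#' fall below; events closer than `merge_ms` are merged. Velocity is a
#' Savitzky-Golay local derivative over `deriv_window` samples (21 ms by
#' default, wide enough to keep drift-like positional noise below the
#' velocity threshold while preserving saccade peaks). Untracked samples
#' never open an event.
#'
#' @param recording A `gaze_recording` (1000 Hz, degrees).
#' @param vel_thresh Velocity threshold, deg/s (default 30).
#' @param acc_thresh Acceleration threshold, deg/s^2 (default 8000).
#' @param merge_ms Merge window for adjacent events, ms (default 20).
#' @param deriv_window Savitzky-Golay derivative window, samples
#'   (default 21).
#' @return Data frame of saccade events: `eye`, `start_time_ms`,
#'   `end_time_ms`, `duration_ms`, `start_x_deg`, `start_y_deg`,
#'   `end_x_deg`, `end_y_deg`, `amplitude_deg`, `peak_velocity_deg_s`,
#'   `angle_deg`, `orientation`.
#' @export
detect_saccades <- function(recording, vel_thresh = 30, acc_thresh = 8000,
                            merge_ms = 20, deriv_window = 21L) {
  stopifnot(inherits(recording, "gaze_recording"))
  fs <- recording$fs
  vx <- sg_derivative(recording$x, fs, deriv_window)
  vy <- sg_derivative(recording$y, fs, deriv_window)
  speed <- sqrt(vx^2 + vy^2)
  acc <- c(0, diff(speed)) * fs
  active <- (speed > vel_thresh | abs(acc) > acc_thresh) & recording$tracked
  active[is.na(active)] <- FALSE
  if (!any(active)) return(empty_saccades())
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_s <- starts[r$values]
  on_e <- ends[r$values]
  # merge events separated by less than merge_ms
  gap <- round(merge_ms / 1000 * fs)
  if (length(on_s) > 1) {
    keep_s <- on_s[1]
    merged_s <- c()
    merged_e <- c()
    cur_s <- on_s[1]
    cur_e <- on_e[1]
    for (i in 2:length(on_s)) {
      if (on_s[i] - cur_e < gap) {
        cur_e <- on_e[i]
      } else {
        merged_s <- c(merged_s, cur_s)
        merged_e <- c(merged_e, cur_e)
        cur_s <- on_s[i]
        cur_e <- on_e[i]
      }
    }
    merged_s <- c(merged_s, cur_s)
    merged_e <- c(merged_e, cur_e)
    on_s <- merged_s
    on_e <- merged_e
  }
  evs <- lapply(seq_along(on_s), function(i) {
    s <- max(on_s[i] - 1L, 1L)  # endpoint just before threshold crossing
    e <- min(on_e[i] + 1L, length(recording$t))
    make_saccade(recording$eye,
                 recording$t[s] * 1000, recording$t[e] * 1000,
                 recording$x[s], recording$y[s],
                 recording$x[e], recording$y[e],
                 max(speed[s:e], na.rm = TRUE))
  })
  do.call(rbind, evs)
}

empty_saccades <- function() {
  data.frame(eye = character(), start_time_ms = numeric(),
             end_time_ms = numeric(), duration_ms = numeric(),
             start_x_deg = numeric(), start_y_deg = numeric(),
             end_x_deg = numeric(), end_y_deg = numeric(),
             amplitude_deg = numeric(), peak_velocity_deg_s = numeric(),
             angle_deg = numeric(), orientation = character(),
             stringsAsFactors = FALSE)
}

make_saccade <- function(eye, t0, t1, sx, sy, ex, ey, pv) {
  amp <- sqrt((ex - sx)^2 + (ey - sy)^2)
  ang <- (atan2(ey - sy, ex - sx) * 180 / pi) %% 360
  data.frame(eye = eye, start_time_ms = t0, end_time_ms = t1,
             duration_ms = t1 - t0,
             start_x_deg = sx, start_y_deg = sy,
             end_x_deg = ex, end_y_deg = ey,
             amplitude_deg = amp, peak_velocity_deg_s = pv,
             angle_deg = ang,
             orientation = classify_orientation(ang),
             stringsAsFactors = FALSE)
}

#' Parse ESACC events from EyeLink-ASCII text
#'
#' Extracts end-saccade (`ESACC`) messages:
#' `ESACC <eye> <start> <end> <dur> <sx> <sy> <ex> <ey> <amp> <pv>`
#' with positions in pixels, converted to center-origin degrees via the
#' display geometry. Lines with missing-data tokens (`.`) are dropped and
#' counted; all non-ESACC lines (SSACC, EFIX, MSG, samples) are ignored.
#' By default the amplitude is recomputed from the converted endpoints;
#' `trust_amplitude = TRUE` keeps the parsed value (which EyeLink reports
#' in degrees).
#'
#' @param lines Character vector of ASCII lines (or a file read with
#'   `readLines`).
#' @param geom A `display_geometry` for the pixel-to-degree conversion.
#' @param trust_amplitude Keep the ESACC amplitude field instead of
#'   recomputing from endpoints.
#' @return Data frame of saccade events (see [detect_saccades()]) with
#'   attributes `n_malformed` and `n_dropped`.
#' @export
parse_esacc <- function(lines, geom = display_geometry(),
                        trust_amplitude = FALSE) {
  sel <- grep("^\\s*ESACC\\b", lines, value = TRUE)
  if (length(sel) == 0) {
    warning("no ESACC lines found")
    out <- empty_saccades()
    attr(out, "n_malformed") <- 0L
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  n_malformed <- 0L
  n_dropped <- 0L
  evs <- list()
  for (ln in sel) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(tok) < 11) {
      n_malformed <- n_malformed + 1L
      next
    }
    fields <- tok[3:11]
    if (any(fields == ".")) {
      n_dropped <- n_dropped + 1L
      next
    }
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num))) {
      n_malformed <- n_malformed + 1L
      next
    }
    s <- pixels_to_degrees(num[4], num[5], geom)
    e <- pixels_to_degrees(num[6], num[7], geom)
    ev <- make_saccade(tok[2], num[1], num[2], s$x, s$y, e$x, e$y, num[9])
    if (trust_amplitude) {
      ev$amplitude_deg <- num[8]
    }
    evs[[length(evs) + 1L]] <- ev
  }
  out <- if (length(evs) > 0) do.call(rbind, evs) else empty_saccades()
  attr(out, "n_malformed") <- n_malformed
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter erroneously recorded saccades
#'
#' Removes events with amplitude above 50 deg (larger than the screen) or
#' below 2 deg (not a response to a stimulus jump), duration below 10 ms or
#' above 150 ms, peak velocity above 750 deg/s, or an endpoint off the
#' screen. All boundaries are inclusive for retention (an event exactly at
#' 2 deg or 10 ms is kept). An event failing several rules is counted once,
#' under the first failing rule in the order amplitude-high, amplitude-low,
#' duration-short, duration-long, velocity, off-screen.
#'
#' @param events Saccade event data frame.
#' @param geom A `display_geometry` defining the screen extent.
#' @return List with `retained` (event data frame) and `report` (named
#'   integer vector of removal counts per rule plus `retained`).
#' @export
filter_saccades <- function(events, geom = display_geometry()) {
  ext <- screen_extent_degrees(geom)
  hx <- ext[1] / 2
  hy <- ext[2] / 2
  rules <- c("amp_gt_50", "amp_lt_2", "dur_lt_10", "dur_gt_150",
             "vel_gt_750", "off_screen")
  counts <- stats::setNames(integer(length(rules)), rules)
  if (nrow(events) == 0)
    return(list(retained = events, report = c(counts, retained = 0L)))
  fail <- cbind(
    amp_gt_50 = events$amplitude_deg > 50,
    amp_lt_2 = events$amplitude_deg < 2,
    dur_lt_10 = events$duration_ms < 10,
    dur_gt_150 = events$duration_ms > 150,
    vel_gt_750 = events$peak_velocity_deg_s > 750,
    off_screen = abs(events$start_x_deg) > hx | abs(events$end_x_deg) > hx |
      abs(events$start_y_deg) > hy | abs(events$end_y_deg) > hy)
  first_fail <- apply(fail, 1, function(f) if (any(f)) which(f)[1] else 0L)
  for (k in seq_along(rules))
    counts[k] <- sum(first_fail == k)
  retained <- events[first_fail == 0L, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       report = c(counts, retained = nrow(retained)))
}

#' Classify saccade orientation from its angle
#'
#' Angles in `[45, 135)` or `[225, 315)` degrees (mathematical convention,
#' up-positive) are vertical; the rest horizontal. Half-open boundaries
#' guarantee a partition of the circle.
#'
#' @param angle_deg Saccade direction angle(s); any real value (reduced
#'   modulo 360).
#' @return Character vector, `"horizontal"` or `"vertical"`.
#' @export
classify_orientation <- function(angle_deg) {
  if (any(is.na(angle_deg))) stop("angle is NA (zero-amplitude event?)")
  a <- angle_deg %% 360
  ifelse((a >= 45 & a < 135) | (a >= 225 & a < 315), "vertical", "horizontal")
}

#' Amplitude summary per participant and orientation
#'
#' @param events Retained saccade event data frame, with a `participant`
#'   column.
#' @return Data frame of per-participant, per-orientation median amplitude
#'   and event count.
#' @export
amplitude_summary <- function(events) {
  if (nrow(events) == 0)
    return(structure(NA, class = "excluded_outcome"))
  agg <- stats::aggregate(amplitude_deg ~ participant + orientation,
                          data = events, FUN = stats::median)
  cnt <- stats::aggregate(amplitude_deg ~ participant + orientation,
                          data = events, FUN = length)
  names(agg)[3] <- "median_amplitude_deg"
  agg$n_saccades <- cnt$amplitude_deg
  agg
}

#' Assemble the main-sequence analysis table
#'
#' One row per retained saccade with amplitude centered on the grand mean,
#' linked to participant metadata (group, viewing condition, age, BCVA).
#' Rows with missing covariates are flagged and excluded from modelling.
#'
#' @param events Retained saccade event data frame with a `participant`
#'   column.
#' @param participants Data frame with columns `participant`, `group`,
#'   `viewing`, `age`, `bcva`.
#' @return Data frame with columns `amplitude_deg`, `amplitude_centered`,
#'   `peak_velocity_deg_s`, `participant`, `group`, `viewing`, `age`,
#'   `bcva`, `complete`.
#' @export
main_sequence_table <- function(events, participants) {
  stopifnot(all(c("participant", "group", "viewing", "age", "bcva") %in%
                  names(participants)))
  tab <- merge(events, participants, by = "participant", sort = FALSE)
  tab$amplitude_centered <- tab$amplitude_deg - mean(tab$amplitude_deg)
  tab$complete <- stats::complete.cases(tab[, c("age", "bcva", "group",
                                                "viewing")])
  tab
}
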