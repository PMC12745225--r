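# Tracking performance: the time-shifted cosine similarity between the
# stimulus and gaze position vectors, evaluated on a grid of delays, with
# the first-positive-peak rule.

#' Cosine similarity between stimulus and gaze position vectors
#'
#' The normalized inner product `A.B / (||A|| ||B||)` over pairwise-complete
#' samples (pairs where either vector is NaN are dropped). Values near 1
#' indicate very good tracking, values near 0 poor tracking. Both vectors
#' should be center-origin degree coordinates; a large common offset (e.g.
#' raw top-left pixel coordinates) would push the similarity toward 1
#' regardless of tracking.
#'
#' @param a Stimulus positions over time (one axis).
#' @param b Gaze positions over time (same axis, may contain NaN).
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !(is.na(a) | is.na(b))
  if (sum(ok) < 2) stop("undefined similarity: fewer than 2 complete pairs")
  a <- a[ok]
  b <- b[ok]
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined similarity: zero-norm vector")
  sum(a * b) / (na * nb)
}

#' Time-shifted cosine similarity function
#'
#' Computes the cosine similarity between stimulus and gaze for a series of
#' delays (default -5 to +5 s in steps of one frame, 1/240 s ~ 0.0042 s).
#' Positive delay means the gaze lags the stimulus: at delay `d` frames,
#' `stimulus[i]` is compared with `gaze[i + d]` on the overlapping window,
#' with pairwise-complete NaN handling.
#'
#' @param stim Stimulus positions (one axis, degrees, center-origin).
#' @param gaze Gaze positions (same axis and length, may contain NaN).
#' @param fs Frame rate, Hz (default 240).
#' @param delay_range_s Length-2 numeric, delay window in seconds
#'   (default `c(-5, 5)`).
#' @return Object of class `sonda_csf`: data frame-like list with
#'   `delay_s`, `value`, plus `peak_delay_s`, `peak_value`, `peak_found`
#'   filled in by the peak rule (see [tracking_performance()]).
#' @examples
#' traj <- generate_smooth_trajectory(seed = 1, duration_s = 10)
#' csf <- similarity_function(traj$x, traj$x)
#' csf$value[csf$delay_s == 0]  # 1: a signal tracks itself perfectly
#' @export
similarity_function <- function(stim, gaze, fs = 240,
                                delay_range_s = c(-5, 5)) {
  stopifnot(length(stim) == length(gaze))
  n <- length(stim)
  dmax <- round(max(abs(delay_range_s)) * fs)
  if (n <= dmax + 2) stop("vectors shorter than the delay window")
  lags <- seq.int(round(delay_range_s[1] * fs), round(delay_range_s[2] * fs))
  ok <- !(is.na(stim) | is.na(gaze))
  vals <- vapply(lags, function(d) {
    if (d >= 0) {
      ia <- seq_len(n - d)
      ib <- ia + d
    } else {
      ib <- seq_len(n + d)
      ia <- ib - d
    }
    a <- stim[ia]
    b <- gaze[ib]
    keep <- !(is.na(a) | is.na(b))
    if (sum(keep) < 2) return(NA_real_)
    a <- a[keep]
    b <- b[keep]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(NA_real_)
    sum(a * b) / den
  }, numeric(1))
  csf <- structure(list(delay_s = lags / fs, value = vals, fs = fs),
                   class = "sonda_csf")
  pk <- tracking_performance(csf)
  csf$peak_delay_s <- attr(pk, "peak_delay_s")
  csf$peak_value <- as.numeric(pk)
  csf$peak_found <- attr(pk, "peak_found")
  csf
}

#' Tracking performance from a cosine similarity function
#'
#' The tracking performance of a trajectory is the value at the first local
#' maximum of the cosine similarity function at positive delay (a local
#' maximum is strictly greater than both neighbours; a plateau maximum is
#' taken at its first sample). If no local maximum exists at positive
#' delays, the maximum similarity over delays in (0, +3] s is used and
#' `peak_found` is FALSE.
#'
#' @param csf A `sonda_csf` from [similarity_function()].
#' @param fallback_window_s Upper edge (inclusive) of the fallback search
#'   window in seconds (default 3).
#' @return The performance value, with attributes `peak_delay_s` and
#'   `peak_found`.
#' @export
tracking_performance <- function(csf, fallback_window_s = 3) {
  stopifnot(inherits(csf, "sonda_csf"))
  d <- csf$delay_s
  v <- csf$value
  n <- length(v)
  # first local maximum (strictly above both distinct neighbours; plateaus
  # reported at their first sample) whose delay is positive
  peak_idx <- NA_integer_
  i <- 2L
  while (i <= n - 1L) {
    if (!is.na(v[i]) && !is.na(v[i - 1L]) && v[i] > v[i - 1L]) {
      k <- i
      while (k < n && !is.na(v[k + 1L]) && v[k + 1L] == v[i]) k <- k + 1L
      if (k < n && !is.na(v[k + 1L]) && v[k + 1L] < v[i] && d[i] > 0) {
        peak_idx <- i
        break
      }
      i <- k + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!is.na(peak_idx)) {
    out <- v[peak_idx]
    attr(out, "peak_delay_s") <- d[peak_idx]
    attr(out, "peak_found") <- TRUE
  } else {
    win <- which(d > 0 & d <= fallback_window_s)
    if (all(is.na(v[win]))) stop("no defined similarity in the fallback window")
    k <- win[which.max(v[win])]
    out <- v[k]
    attr(out, "peak_delay_s") <- d[k]
    attr(out, "peak_found") <- FALSE
  }
  out
}

#' @export
print.sonda_csf <- function(x, ...) {
  cat(sprintf("Cosine similarity function: %d delays in [%g, %g] s\n",
              length(x$delay_s), min(x$delay_s), max(x$delay_s)))
  if (!is.null(x$peak_value))
    cat(sprintf("  tracking performance %.4f at delay %+.4f s (%s)\n",
                x$peak_value, x$peak_delay_s,
                if (x$peak_found) "first positive peak"
                else "fallback max on (0, 3] s"))
  invisible(x)
}

#' @export
plot.sonda_csf <- function(x, ...) {
  graphics::plot(x$delay_s, x$value, type = "l",
                 xlab = "delay (s)", ylab = "cosine similarity", ...)
  if (!is.null(x$peak_value))
    graphics::points(x$peak_delay_s, x$peak_value, col = 2, pch = 19)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Aggregate per-trajectory tracking performance to final outcomes
#'
#' Saccadic-mode performance is the mean over the (retained) saccadic
#' trajectories; binocular performance is computed per eye and then
#' averaged. Horizontal and vertical axes are reported separately.
#'
#' @param values Numeric vector of per-trajectory (or per-eye) performance
#'   values.
#' @return Their arithmetic mean; NA with class `excluded_outcome` when
#'   empty.
#' @export
aggregate_performance <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    return(structure(NA_real_, class = "excluded_outcome"))
  mean(values)
}

#' Tracking outcome for one participant-condition
#'
#' Runs the similarity analysis for every retained trajectory, axis and
#' eye, and aggregates per the mode/viewing rules.
#'
#' @param pairs List of retained `clean_pair` objects (one per trajectory
#'   and eye).
#' @param delay_range_s Delay window passed to [similarity_function()].
#' @return Data frame with one row per mode x axis: columns `participant`,
#'   `viewing`, `mode`, `axis`, `performance`, `n_trajectories`.
#' @export
tracking_outcomes <- function(pairs, delay_range_s = c(-5, 5)) {
  rows <- list()
  modes <- unique(vapply(pairs, function(p) p$mode, ""))
  for (mode in modes) {
    sel <- pairs[vapply(pairs, function(p) p$mode == mode, TRUE)]
    for (axis in c("horizontal", "vertical")) {
      per_eye <- tapply(seq_along(sel),
                        vapply(sel, function(p) p$eye, ""),
                        function(ii) {
        vals <- vapply(sel[ii], function(p) {
          stim <- if (axis == "horizontal") p$stim_x else p$stim_y
          gaze <- if (axis == "horizontal") p$gaze_x else p$gaze_y
          csf <- similarity_function(stim, gaze, fs = p$fs,
                                     delay_range_s = delay_range_s)
          csf$peak_value
        }, numeric(1))
        mean(vals)
      })
      perf <- aggregate_performance(unlist(per_eye))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sel[[1]]$participant_id,
        viewing = sel[[1]]$viewing, mode = mode, axis = axis,
        performance = as.numeric(perf),
        n_trajectories = length(unique(vapply(
          sel, function(p) as.numeric(p$trajectory_seed %||% 0), numeric(1)))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
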