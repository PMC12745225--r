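# Synchronization between the eyes: per-sample OD - OS positional
# differences and their trajectory summaries.

#' Per-sample positional difference between the eyes
#'
#' OD minus OS per axis, per sample (binocular viewing only). NaN wherever
#' either eye is NaN. With the up-positive, rightward-positive degree
#' convention used throughout, a positive horizontal difference means OD
#' pointed further right than OS; on the histogram convention in which
#' positive means "further left on the screen", flip the sign of x
#' (`screen_left_positive = TRUE`).
#'
#' @param od_pair,os_pair `clean_pair` objects for the right and left eye
#'   of the same trajectory, or plain numeric vectors via `od_x`-style
#'   arguments below.
#' @param screen_left_positive Flip the horizontal sign so positive means
#'   OD further left on the screen (default FALSE).
#' @return List with per-sample `dx`, `dy` difference series in degrees.
#' @export
positional_difference <- function(od_pair, os_pair,
                                  screen_left_positive = FALSE) {
  stopifnot(inherits(od_pair, "clean_pair"), inherits(os_pair, "clean_pair"))
  if (od_pair$viewing != "binocular" || os_pair$viewing != "binocular")
    stop("positional difference requires binocular viewing")
  stopifnot(od_pair$eye == "OD", os_pair$eye == "OS",
            length(od_pair$gaze_x) == length(os_pair$gaze_x))
  dx <- od_pair$gaze_x - os_pair$gaze_x
  dy <- od_pair$gaze_y - os_pair$gaze_y
  if (screen_left_positive) dx <- -dx
  list(dx = dx, dy = dy)
}

#' Summarize positional differences over trajectories
#'
#' Each trajectory's difference series is averaged over its non-NaN
#' samples; for the saccadic pursuit mode these trajectory means are then
#' averaged over the three trajectories. The absolute statistic is the
#' absolute value of each trajectory mean, averaged over trajectories
#' (`per_sample_absolute = TRUE` instead averages `|difference|` per sample
#' before the trajectory mean).
#'
#' @param diffs List of per-trajectory difference series (each a list with
#'   `dx`, `dy`, as returned by [positional_difference()]).
#' @param per_sample_absolute Use the per-sample absolute variant.
#' @return Data frame with one row per axis: `axis`,
#'   `signed_pos_diff_deg`, `abs_pos_diff_deg`, `n_trajectories`.
#' @export
summarize_difference <- function(diffs, per_sample_absolute = FALSE) {
  stopifnot(length(diffs) >= 1)
  per_traj <- lapply(diffs, function(d) {
    sx <- mean(d$dx, na.rm = TRUE)
    sy <- mean(d$dy, na.rm = TRUE)
    ax <- if (per_sample_absolute) mean(abs(d$dx), na.rm = TRUE) else abs(sx)
    ay <- if (per_sample_absolute) mean(abs(d$dy), na.rm = TRUE) else abs(sy)
    c(sx = sx, sy = sy, ax = ax, ay = ay)
  })
  m <- do.call(rbind, per_traj)
  if (all(is.nan(m)))
    return(structure(NA, class = "excluded_outcome"))
  data.frame(
    axis = c("horizontal", "vertical"),
    signed_pos_diff_deg = c(mean(m[, "sx"], na.rm = TRUE),
                            mean(m[, "sy"], na.rm = TRUE)),
    abs_pos_diff_deg = c(mean(m[, "ax"], na.rm = TRUE),
                         mean(m[, "ay"], na.rm = TRUE)),
    n_trajectories = nrow(m),
    stringsAsFactors = FALSE)
}

#' Binocular synchronization outcome for one participant-condition
#'
#' Pairs OD/OS clean pairs by trajectory and mode, computes per-sample
#' differences, and summarizes per mode.
#'
#' @param pairs List of retained `clean_pair` objects (both eyes).
#' @param ... Passed to [summarize_difference()].
#' @return Data frame with one row per mode x axis.
#' @export
binocular_outcomes <- function(pairs, ...) {
  eyes <- vapply(pairs, function(p) p$eye, "")
  seeds <- vapply(pairs, function(p) as.integer(p$trajectory_seed), 0L)
  modes <- vapply(pairs, function(p) p$mode, "")
  rows <- list()
  for (mode in unique(modes)) {
    idx <- which(modes == mode)
    diffs <- list()
    for (s in unique(seeds[idx])) {
      od <- idx[seeds[idx] == s & eyes[idx] == "OD"]
      os <- idx[seeds[idx] == s & eyes[idx] == "OS"]
      if (length(od) == 1 && length(os) == 1)
        diffs[[length(diffs) + 1L]] <-
          positional_difference(pairs[[od]], pairs[[os]])
    }
    if (length(diffs) == 0) next
    sm <- summarize_difference(diffs, ...)
    if (inherits(sm, "excluded_outcome")) next
    sm$participant <- pairs[[idx[1]]]$participant_id
    sm$mode <- mode
    rows[[length(rows) + 1L]] <- sm
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
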