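#' Humphrey 24-2 style target grid
#'
#' The 54 test locations of the standard 24-2 visual-field grid (6-degree
#' spacing, two extra locations at 27 degrees eccentricity on the horizontal
#' rows), optionally scaled so the whole grid fits within a display's angular
#' extent with a safety margin.
#'
#' @param geom A `display_geometry`, or NULL to return the unscaled grid.
#' @param margin Fraction of the half-extent the grid may occupy (default 0.92).
#' @return Data frame with columns `x`, `y` in degrees (center-origin).
#' @export
hfa24_2_grid <- function(geom = NULL, margin = 0.92) {
  rows <- list(
    `21` = c(-9, -3, 3, 9),
    `15` = c(-15, -9, -3, 3, 9, 15),
    `9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`  = c(-21, -15, -9, -3, 3, 9, 15, 21, 27))
  pts <- do.call(rbind, lapply(names(rows), function(yy) {
    y <- as.numeric(yy)
    rbind(data.frame(x = rows[[yy]], y = y),
          data.frame(x = rows[[yy]], y = -y))
  }))
  if (!is.null(geom)) {
    ext <- screen_extent_degrees(geom)
    s <- min(margin * ext[1] / 2 / max(abs(pts$x)),
             margin * ext[2] / 2 / max(abs(pts$y)))
    pts$x <- pts$x * s
    pts$y <- pts$y * s
  }
  rownames(pts) <- NULL
  pts
}

# Smoothed random walk on heading and speed; one step per frame, reflected
# toward the screen center when the path approaches the edge.
smooth_path <- function(n, geom, mean_speed = 8, max_speed = 15,
                        min_speed = 1, turn_sd = 2.5, speed_sd = 4) {
  ext <- screen_extent_degrees(geom)
  bx <- 0.95 * ext[1] / 2
  by <- 0.95 * ext[2] / 2
  dt <- 1 / geom$refresh_hz
  x <- y <- numeric(n)
  heading <- stats::runif(1, 0, 2 * pi)
  speed <- mean_speed
  turn_noise <- stats::rnorm(n, 0, turn_sd * sqrt(dt))
  speed_noise <- stats::rnorm(n, 0, speed_sd * sqrt(dt))
  for (i in seq_len(n - 1)) {
    heading <- heading + turn_noise[i]
    speed <- speed + 2 * (mean_speed - speed) * dt + speed_noise[i]
    speed <- min(max(speed, min_speed), max_speed)
    nx <- x[i] + speed * dt * cos(heading)
    ny <- y[i] + speed * dt * sin(heading)
    if (abs(nx) > bx || abs(ny) > by) {
      # steer back toward the center with a little jitter
      heading <- atan2(-y[i], -x[i]) + stats::rnorm(1, 0, 0.3)
      nx <- x[i] + speed * dt * cos(heading)
      ny <- y[i] + speed * dt * sin(heading)
      nx <- min(max(nx, -bx), bx)
      ny <- min(max(ny, -by), by)
    }
    x[i + 1] <- nx
    y[i + 1] <- ny
  }
  list(x = x, y = y)
}

new_trajectory <- function(mode, t, x, y, jumps, duration_s, seed, geom) {
  structure(list(mode = mode, t = t, x = x, y = y, jumps = jumps,
                 duration_s = duration_s, seed = seed, geom = geom),
            class = "stimulus_trajectory")
}

#' Generate a smooth pursuit stimulus trajectory
#'
#' The stimulus moves continuously from the screen center; direction and
#' speed vary pseudo-randomly (a smoothed random walk on heading with a
#' mean-reverting speed process), bounded so the path stays on screen.
#' Deterministic given `seed`.
#'
#' @param seed Integer RNG seed.
#' @param duration_s Trajectory duration in seconds (default 40).
#' @param geom A `display_geometry` (default the standard 240 Hz setup).
#' @param mean_speed,max_speed,min_speed Speed process bounds in deg/s.
#' @param turn_sd Heading diffusion in rad/sqrt(s).
#' @param speed_sd Speed diffusion in deg/s/sqrt(s).
#' @return A `stimulus_trajectory` with `mode = "smooth"`, sampled at the
#'   display refresh rate; first sample at (0, 0).
#' @export
generate_smooth_trajectory <- function(seed, duration_s = 40,
                                       geom = display_geometry(),
                                       mean_speed = 8, max_speed = 15,
                                       min_speed = 1,
                                       turn_sd = 2.5, speed_sd = 4) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * geom$refresh_hz)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- smooth_path(n, geom, mean_speed, max_speed, min_speed, turn_sd, speed_sd)
  new_trajectory("smooth", (seq_len(n) - 1) / geom$refresh_hz, p$x, p$y,
                 jumps = empty_jumps(), duration_s, seed, geom)
}

empty_jumps <- function() {
  data.frame(frame_index = integer(), from_x = numeric(), from_y = numeric(),
             to_x = numeric(), to_y = numeric())
}

#' Generate a saccadic pursuit stimulus trajectory
#'
#' Smooth motion as in [generate_smooth_trajectory()], interleaved with
#' instantaneous jumps to visual-field test locations. By default 18 jumps
#' are placed in a 40 s trajectory, uniformly spaced in time with 20% jitter,
#' so three trajectories jointly cover the 54-point grid without replacement.
#'
#' @param seed Integer RNG seed.
#' @param duration_s Duration in seconds (default 40).
#' @param geom A `display_geometry`.
#' @param target_grid Data frame of candidate jump targets (`x`, `y` in
#'   degrees); defaults to [hfa24_2_grid()] scaled to the screen.
#' @param targets Optional data frame of the exact jump targets to visit in
#'   order (used by [generate_trajectory_set()] to partition the grid); when
#'   NULL, `n_jumps` targets are sampled from `target_grid` without
#'   replacement.
#' @param n_jumps Number of jumps (default 18).
#' @param ... Passed to the smooth-motion process.
#' @return A `stimulus_trajectory` with `mode = "saccadic"` and one row in
#'   `$jumps` per jump (frame index, origin and landing position).
#' @export
generate_saccadic_trajectory <- function(seed, duration_s = 40,
                                         geom = display_geometry(),
                                         target_grid = hfa24_2_grid(geom),
                                         targets = NULL, n_jumps = 18, ...) {
  stopifnot(duration_s > 0, nrow(target_grid) > 0)
  ext <- screen_extent_degrees(geom)
  if (any(abs(target_grid$x) > ext[1] / 2 | abs(target_grid$y) > ext[2] / 2))
    stop("target grid points outside screen extent")
  n <- round(duration_s * geom$refresh_hz)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(targets)) {
    idx <- sample.int(nrow(target_grid), min(n_jumps, nrow(target_grid)))
    targets <- target_grid[idx, , drop = FALSE]
  }
  k <- nrow(targets)
  x <- y <- numeric(n)
  jumps <- empty_jumps()
  if (k > 0) {
    # uniformly spaced jump times with +/-20% jitter, none in the first second
    slot <- (duration_s - 1) / k
    times <- 1 + (seq_len(k) - 0.5) * slot +
      stats::runif(k, -0.2 * slot, 0.2 * slot)
    frames <- sort(pmin(pmax(round(times * geom$refresh_hz), 2L), n - 1L))
  } else frames <- integer()
  seg_start <- c(1L, frames + 1L)
  seg_end <- c(frames, n)
  pos <- c(0, 0)
  for (s in seq_along(seg_start)) {
    len <- seg_end[s] - seg_start[s] + 1L
    p <- smooth_path(len, geom, ...)
    x[seg_start[s]:seg_end[s]] <- pos[1] + p$x - p$x[1]
    y[seg_start[s]:seg_end[s]] <- pos[2] + p$y - p$y[1]
    # keep the offset segment on screen
    x[seg_start[s]:seg_end[s]] <- pmin(pmax(x[seg_start[s]:seg_end[s]],
                                            -ext[1] / 2), ext[1] / 2)
    y[seg_start[s]:seg_end[s]] <- pmin(pmax(y[seg_start[s]:seg_end[s]],
                                            -ext[2] / 2), ext[2] / 2)
    if (s <= length(frames)) {
      # frame_index is the landing frame: the first sample at the new location
      jumps <- rbind(jumps, data.frame(
        frame_index = frames[s] + 1L,
        from_x = x[seg_end[s]], from_y = y[seg_end[s]],
        to_x = targets$x[s], to_y = targets$y[s]))
      pos <- c(targets$x[s], targets$y[s])
    }
  }
  new_trajectory("saccadic", (seq_len(n) - 1) / geom$refresh_hz, x, y,
                 jumps, duration_s, seed, geom)
}

#' Generate a full trajectory set
#'
#' One experimental set: a single smooth pursuit trajectory plus three
#' saccadic pursuit trajectories of 40 s each. The three saccadic
#' trajectories partition the 54-point target grid (18 jumps each), so
#' together they sample the whole visual field exactly once.
#'
#' @param seed Integer RNG seed.
#' @param duration_s Per-trajectory duration (default 40 s).
#' @param geom A `display_geometry`.
#' @return A list of class `trajectory_set` with elements `smooth`
#'   (one trajectory) and `saccadic` (list of three).
#' @export
generate_trajectory_set <- function(seed, duration_s = 40,
                                    geom = display_geometry()) {
  grid <- hfa24_2_grid(geom)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(nrow(grid))
  sub_seeds <- sample.int(.Machine$integer.max, 4L)
  parts <- split(perm, rep(1:3, each = ceiling(nrow(grid) / 3))[seq_along(perm)])
  smooth <- generate_smooth_trajectory(sub_seeds[1], duration_s, geom)
  saccadic <- lapply(1:3, function(i)
    generate_saccadic_trajectory(sub_seeds[i + 1], duration_s, geom,
                                 target_grid = grid,
                                 targets = grid[parts[[i]], , drop = FALSE]))
  structure(list(smooth = smooth, saccadic = saccadic, seed = seed,
                 geom = geom),
            class = "trajectory_set")
}

#' @export
print.stimulus_trajectory <- function(x, ...) {
  cat(sprintf("Stimulus trajectory: %s pursuit, %g s at %g Hz (%d samples)",
              x$mode, x$duration_s, x$geom$refresh_hz, length(x$t)))
  if (nrow(x$jumps) > 0) cat(sprintf(", %d jumps", nrow(x$jumps)))
  cat("\n")
  invisible(x)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set (seed %s): 1 smooth + %d saccadic, %g s each\n",
              format(x$seed), length(x$saccadic), x$smooth$duration_s))
  invisible(x)
}

#' @export
plot.stimulus_trajectory <- function(x, ...) {
  ext <- screen_extent_degrees(x$geom)
  graphics::plot(x$x, x$y, type = "l", xlim = c(-1, 1) * ext[1] / 2,
                 ylim = c(-1, 1) * ext[2] / 2, asp = 1,
                 xlab = "horizontal (deg)", ylab = "vertical (deg)",
                 main = sprintf("%s pursuit trajectory", x$mode), ...)
  if (nrow(x$jumps) > 0)
    graphics::points(x$jumps$to_x, x$jumps$to_y, pch = 4, col = 2)
  invisible(x)
}

# Save/restore the global RNG state so generators are pure in their seed
# without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
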