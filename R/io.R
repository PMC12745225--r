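# Tabular text formats: one TSV per trajectory x eye for gaze
# (columns t_ms, x_deg, y_deg, tracked; '#'-prefixed metadata header) and
# one TSV per stimulus trajectory (t_ms, x_deg, y_deg, jump).

#' Write a gaze recording to a TSV file
#'
#' @param recording A `gaze_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  header <- c(
    paste0("# participant\t", recording$participant_id),
    paste0("# eye\t", recording$eye),
    paste0("# viewing\t", recording$viewing),
    paste0("# mode\t", recording$mode),
    paste0("# seed\t", recording$trajectory_seed),
    paste0("# fs\t", recording$fs))
  df <- data.frame(t_ms = recording$t * 1000,
                   x_deg = recording$x, y_deg = recording$y,
                   tracked = as.integer(recording$tracked))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gaze recording from a TSV file
#'
#' Inverse of [write_recording()]; NaN cells round-trip as NaN.
#'
#' @param path File path.
#' @return A `gaze_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\t")[[1]]
    if (length(parts) == 2) meta[[parts[1]]] <- parts[2]
  }
  body_start <- length(hdr) + 1L
  cols <- strsplit(lines[body_start], "\t")[[1]]
  required <- c("t_ms", "x_deg", "y_deg", "tracked")
  if (!all(required %in% cols))
    stop(sprintf("parse error at line %d: missing column(s) %s",
                 body_start, paste(setdiff(required, cols), collapse = ", ")))
  df <- utils::read.table(text = lines[-seq_len(body_start)], sep = "\t",
                          col.names = cols, na.strings = "NA")
  # masked cells are stored as NaN; keep them NaN (not NA) on the way back
  df$x_deg[is.na(df$x_deg)] <- NaN
  df$y_deg[is.na(df$y_deg)] <- NaN
  fs <- as.numeric(meta$fs %||% 1000)
  structure(list(participant_id = meta$participant %||% NA_character_,
                 eye = meta$eye %||% NA_character_,
                 viewing = meta$viewing %||% NA_character_,
                 t = df$t_ms / 1000, x = df$x_deg, y = df$y_deg,
                 tracked = df$tracked == 1, fs = fs,
                 mode = meta$mode %||% NA_character_,
                 trajectory_seed = as.integer(meta$seed %||% NA)),
            class = "gaze_recording")
}

#' Write a stimulus trajectory to a TSV file
#'
#' Columns `t_ms, x_deg, y_deg, jump`; `jump = 1` flags each landing frame.
#'
#' @param trajectory A `stimulus_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "stimulus_trajectory"))
  jump <- integer(length(trajectory$t))
  jump[trajectory$jumps$frame_index] <- 1L
  header <- c(paste0("# mode\t", trajectory$mode),
              paste0("# seed\t", trajectory$seed),
              paste0("# fs\t", trajectory$geom$refresh_hz))
  df <- data.frame(t_ms = trajectory$t * 1000, x_deg = trajectory$x,
                   y_deg = trajectory$y, jump = jump)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulus trajectory from a TSV file
#'
#' @param path File path.
#' @param geom A `display_geometry` to attach (defaults to the standard one).
#' @return A `stimulus_trajectory`. Jump origins/landings are reconstructed
#'   from the samples around each flagged landing frame.
#' @export
read_stimulus <- function(path, geom = display_geometry()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\t")[[1]]
    if (length(parts) == 2) meta[[parts[1]]] <- parts[2]
  }
  body_start <- length(hdr) + 1L
  cols <- strsplit(lines[body_start], "\t")[[1]]
  required <- c("t_ms", "x_deg", "y_deg", "jump")
  if (!all(required %in% cols))
    stop(sprintf("parse error at line %d: missing column(s) %s",
                 body_start, paste(setdiff(required, cols), collapse = ", ")))
  df <- utils::read.table(text = lines[-seq_len(body_start)], sep = "\t",
                          col.names = cols)
  land <- which(df$jump == 1L)
  jumps <- if (length(land) > 0) {
    data.frame(frame_index = land,
               from_x = df$x_deg[land - 1], from_y = df$y_deg[land - 1],
               to_x = df$x_deg[land], to_y = df$y_deg[land])
  } else empty_jumps()
  n <- nrow(df)
  fs <- as.numeric(meta$fs %||% geom$refresh_hz)
  new_trajectory(meta$mode %||% "smooth", df$t_ms / 1000, df$x_deg, df$y_deg,
                 jumps, duration_s = n / fs,
                 seed = as.integer(meta$seed %||% NA), geom = geom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
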