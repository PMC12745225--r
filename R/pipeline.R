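# Orchestration: configuration defaults, cohort simulation, the full
# simulate -> preprocess -> outcomes -> statistics pipeline, and small
# bundled fixtures for the test suite.

#' Analysis configuration with standard defaults
#'
#' All numeric thresholds of the analysis in one place: display geometry,
#' pre-processing limits (750 deg/s velocity filter, plateau rule, 0.05 s
#' NaN padding, 0.5 discard fraction), similarity settings (delays -5..+5 s
#' in steps of one frame, 3 s fallback window), saccade parser and filter
#' thresholds (30 deg/s, 8000 deg/s^2; 2-50 deg, 10-150 ms, 750 deg/s,
#' on-screen), and statistics settings (FDR per outcome family, 5000
#' bootstrap replications).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `sonda_config`.
#' @export
sonda_config <- function(...) {
  cfg <- list(
    geometry = display_geometry(24.5, c(1920L, 1080L), 240, 60),
    trajectory_duration_s = 40,
    vel_limit = 750,
    plateau_steps = 2L,
    per_axis_velocity = FALSE,
    pad_s = 0.05,
    discard_fraction = 0.5,
    delay_range_s = c(-5, 5),
    fallback_window_s = 3,
    detect_vel_thresh = 30,
    detect_acc_thresh = 8000,
    filter_amp_deg = c(2, 50),
    filter_dur_ms = c(10, 150),
    filter_vel_deg_s = 750,
    n_bootstrap = 5000,
    bootstrap_type = "parametric",
    ci_method = "percentile")
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  utils::modifyList(cfg, over)
}

#' Simulate one participant-condition through pre-processing
#'
#' Generates a trajectory set, simulates gaze for the requested eyes with
#' the given profile, and pre-processes every trajectory x eye pair,
#' applying the set-level discard rules.
#'
#' @param seed Integer seed for the trajectory set.
#' @param profile An `oculomotor_profile`.
#' @param eyes `c("OD", "OS")` (binocular) or one eye (monocular).
#' @param participant_id Identifier.
#' @param config A `sonda_config`.
#' @return List with `retained` clean pairs, the discard `report`, the
#'   trajectory `set`, and all simulated `recordings`.
#' @export
simulate_participant <- function(seed, profile, eyes = c("OD", "OS"),
                                 participant_id = "sim",
                                 config = sonda_config()) {
  geom <- config$geometry
  set <- generate_trajectory_set(seed, config$trajectory_duration_s, geom)
  trajs <- c(list(set$smooth), set$saccadic)
  pairs <- list()
  recs <- list()
  for (tr in trajs) {
    g <- simulate_gaze(tr, profile, eyes, participant_id)
    for (r in g) {
      pairs[[length(pairs) + 1L]] <- preprocess_recording(
        r, tr, geom, vel_limit = config$vel_limit,
        plateau_steps = config$plateau_steps,
        per_axis = config$per_axis_velocity, pad_s = config$pad_s,
        discard_fraction = config$discard_fraction)
      recs[[length(recs) + 1L]] <- r
    }
  }
  # discard rules act per trajectory (an eye's NaN excess discards the pair)
  by_eye <- split(pairs, vapply(pairs, function(p) p$eye, ""))
  retained <- list()
  reports <- list()
  for (e in names(by_eye)) {
    dr <- apply_discard_rules(by_eye[[e]])
    retained <- c(retained, dr$retained)
    dr$report$eye <- e
    reports[[e]] <- dr$report
  }
  list(retained = retained, report = do.call(rbind, reports),
       set = set, recordings = recs)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates `n_control` healthy-preset and `n_case` case-preset
#' participants (binocular viewing), pre-processes all recordings, computes
#' tracking-performance and binocular-synchronization outcomes, detects and
#' filters saccades, and (when both groups have at least three members)
#' runs the covariate-adjusted group comparisons with FDR control per
#' outcome family and the bootstrap main-sequence model.
#'
#' @param n_control,n_case Participants per group.
#' @param seed Master seed; every stage derives its stream from it.
#' @param config A `sonda_config`.
#' @param out_dir Optional directory; when given, outcome tables (CSV), the
#'   quality report and the statistics report (JSON) are written there.
#' @param n_bootstrap Override of `config$n_bootstrap` for the
#'   main-sequence model.
#' @return List with `tracking`, `binocular`, `amplitudes`, `saccades`,
#'   `quality`, `participants`, `comparisons`, `main_sequence`.
#' @export
run_pipeline <- function(n_control = 3, n_case = 3, seed = 1,
                         config = sonda_config(), out_dir = NULL,
                         n_bootstrap = 500) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_control + n_case
  seeds <- sample.int(2^30, 3 * n)
  groups <- rep(c("control", "case"), c(n_control, n_case))
  ages <- round(stats::runif(n, 40, 75))
  bcva <- round(stats::rnorm(n, 0, 0.08), 2)

  tracking <- list()
  binoc <- list()
  saccades <- list()
  quality <- list()
  for (i in seq_len(n)) {
    id <- sprintf("P%02d", i)
    prof <- if (groups[i] == "control")
      healthy_profile(rng_seed = seeds[n + i])
    else case_profile(rng_seed = seeds[n + i])
    sim <- simulate_participant(seeds[i], prof, c("OD", "OS"), id, config)
    qr <- sim$report
    qr$participant <- id
    quality[[i]] <- qr
    if (length(sim$retained) > 0) {
      tr <- tracking_outcomes(sim$retained, config$delay_range_s)
      tr$group <- groups[i]
      tracking[[i]] <- tr
      bo <- binocular_outcomes(sim$retained)
      if (!is.null(bo)) {
        bo$group <- groups[i]
        binoc[[i]] <- bo
      }
    }
    # saccades from the saccadic-mode recordings (both eyes)
    evs <- lapply(sim$recordings, function(r) {
      if (r$mode != "saccadic") return(NULL)
      detect_saccades(r, config$detect_vel_thresh, config$detect_acc_thresh)
    })
    evs <- do.call(rbind, evs[!vapply(evs, is.null, TRUE)])
    if (!is.null(evs) && nrow(evs) > 0) {
      fl <- filter_saccades(evs, config$geometry)
      if (nrow(fl$retained) > 0) {
        fl$retained$participant <- id
        saccades[[i]] <- fl$retained
      }
    }
  }
  tracking <- do.call(rbind, tracking[!vapply(tracking, is.null, TRUE)])
  binoc <- do.call(rbind, binoc[!vapply(binoc, is.null, TRUE)])
  saccades <- do.call(rbind, saccades[!vapply(saccades, is.null, TRUE)])
  quality <- do.call(rbind, quality)
  participants <- data.frame(participant = sprintf("P%02d", seq_len(n)),
                             group = groups, viewing = "binocular",
                             age = ages, bcva = bcva,
                             stringsAsFactors = FALSE)

  comparisons <- NULL
  ms_fit <- NULL
  amp <- NULL
  if (!is.null(saccades)) amp <- amplitude_summary(saccades)
  if (n_control >= 3 && n_case >= 3) {
    comparisons <- outcome_comparisons(tracking, binoc, amp, participants)
    if (!is.null(saccades)) {
      tab <- main_sequence_table(saccades, participants)
      ms_fit <- fit_main_sequence(tab, n_bootstrap = n_bootstrap,
                                  type = config$bootstrap_type,
                                  ci_method = config$ci_method,
                                  seed = seed)
    }
  }
  res <- list(tracking = tracking, binocular = binoc, amplitudes = amp,
              saccades = saccades, quality = quality,
              participants = participants, comparisons = comparisons,
              main_sequence = ms_fit)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# One FDR family per outcome table, mirroring the standard reporting:
# tracking performance (mode x axis), positional difference (mode x axis),
# median amplitude (orientation).
outcome_comparisons <- function(tracking, binoc, amp, participants) {
  fam <- list()
  add <- function(df, value_col, by_cols, family) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- merge(df, participants[, c("participant", "group", "age", "bcva")],
                by = "participant",
                suffixes = c(".dup", ""))
    keys <- unique(df[, by_cols, drop = FALSE])
    for (r in seq_len(nrow(keys))) {
      sel <- rep(TRUE, nrow(df))
      for (cc in by_cols) sel <- sel & df[[cc]] == keys[r, cc]
      d <- df[sel, ]
      if (length(unique(d$group)) < 2 || min(table(d$group)) < 3) next
      nm <- paste(c(family, unlist(keys[r, ])), collapse = "_")
      res <- try(compare_groups(d[[value_col]], factor(d$group,
                                levels = c("control", "case")),
                                d$age, d$bcva, name = nm), silent = TRUE)
      if (!inherits(res, "try-error")) {
        res$family <- family
        fam[[length(fam) + 1L]] <<- res
      }
    }
  }
  add(tracking, "performance", c("mode", "axis"), "tracking")
  add(binoc, "abs_pos_diff_deg", c("mode", "axis"), "pos_diff")
  add(amp, "median_amplitude_deg", "orientation", "amplitude")
  if (length(fam) == 0) return(NULL)
  out <- do.call(rbind, fam)
  for (f in unique(out$family))
    out$q_value[out$family == f] <- fdr_adjust(out$p_value[out$family == f])
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(res$tracking, "tracking_outcomes.csv")
  wr(res$binocular, "binocular_outcomes.csv")
  wr(res$amplitudes, "amplitude_outcomes.csv")
  wr(res$saccades, "saccade_table.csv")
  wr(res$comparisons, "group_comparisons.csv")
  jsonlite::write_json(res$quality, file.path(out_dir, "quality_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(res$main_sequence)) {
    ms <- res$main_sequence
    jsonlite::write_json(
      list(estimates = ms$estimates, shapiro_W = ms$shapiro_W,
           shapiro_p = ms$shapiro_p, n_bootstrap = ms$n_bootstrap,
           bootstrap_type = ms$bootstrap_type, ci_method = ms$ci_method,
           seed = ms$seed),
      file.path(out_dir, "main_sequence_fit.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Generate a small bundled test dataset
#'
#' Two participants (one healthy preset, one case preset), one binocular
#' trajectory set each, written as TSV recordings plus stimulus files.
#' Regeneration with the same seed is bit-identical.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param duration_s Per-trajectory duration (default 10 s, keeping the
#'   fixtures small and fast).
#' @return `dir`, invisibly; files named
#'   `<participant>_<mode><k>_<eye>.tsv` and `stim_<participant>_<mode><k>.tsv`.
#' @export
make_fixtures <- function(dir, seed = 1, duration_s = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sonda_config(trajectory_duration_s = duration_s)
  specs <- list(healthy = healthy_profile(rng_seed = seed + 1),
                case = case_profile(rng_seed = seed + 2))
  for (nm in names(specs)) {
    set <- generate_trajectory_set(seed + match(nm, names(specs)) * 100,
                                   duration_s, cfg$geometry)
    trajs <- c(list(set$smooth), set$saccadic)
    labels <- c("smooth1", "saccadic1", "saccadic2", "saccadic3")
    for (i in seq_along(trajs)) {
      write_stimulus(trajs[[i]],
                     file.path(dir, sprintf("stim_%s_%s.tsv", nm, labels[i])))
      g <- simulate_gaze(trajs[[i]], specs[[nm]], c("OD", "OS"), nm)
      for (r in g)
        write_recording(r, file.path(dir, sprintf("%s_%s_%s.tsv",
                                                  nm, labels[i], r$eye)))
    }
  }
  invisible(dir)
}
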