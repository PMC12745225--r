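# Group statistics: covariate-adjusted OLS group comparisons with FDR
# control, Mann-Whitney demographic tests, and the bootstrap mixed-effects
# main-sequence model.

#' Covariate-adjusted group comparison for one outcome
#'
#' Ordinary least-squares regression of the outcome on a group indicator
#' with age and best-corrected visual acuity (BCVA) as covariates; the
#' group coefficient's two-sided p-value is the test of interest. Outcomes
#' are analyzed separately per viewing condition, axis and pursuit mode and
#' collected into a family for FDR adjustment with [fdr_adjust()].
#'
#' @param outcome Numeric outcome values.
#' @param group Factor or character group labels (2 levels; the second
#'   level's effect relative to the first is reported).
#' @param age,bcva Covariates, same length.
#' @param name Outcome name carried into the result.
#' @return One-row data frame of class `comparison_result`: `outcome`,
#'   `estimate`, `se`, `p_value`, `age_estimate`, `bcva_estimate`, `n`
#'   (and `q_value = NA` until FDR adjustment).
#' @export
compare_groups <- function(outcome, group, age, bcva, name = "outcome") {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2)
  if (min(table(group)) < 3) stop("fewer than 3 observations in a group")
  if (anyNA(age) || anyNA(bcva)) stop("covariates must be complete")
  df <- data.frame(outcome = outcome, group = group, age = age, bcva = bcva)
  fit <- stats::lm(outcome ~ group + age + bcva, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  res <- data.frame(
    outcome = name,
    estimate = cf[2, "Estimate"], se = cf[2, "Std. Error"],
    p_value = cf[2, "Pr(>|t|)"],
    age_estimate = cf["age", "Estimate"],
    bcva_estimate = cf["bcva", "Estimate"],
    q_value = NA_real_, n = nrow(df),
    stringsAsFactors = FALSE)
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment within a family
#'
#' Step-up q-values for one family of tests (e.g. the 8 tracking-performance
#' comparisons). Wraps `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order; `q >= p` elementwise.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test for demographic differences
#'
#' Two-sided Wilcoxon rank-sum test (with tie correction) for differences
#' in age or BCVA between cases and controls.
#'
#' @param a,b Numeric samples for the two groups.
#' @return List with `U` (the rank-sum statistic for `a`), `p_value`.
#' @export
demographic_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Fit the main-sequence mixed-effects model
#'
#' Linear mixed-effects regression of saccade peak velocity on mean-centered
#' amplitude, group and viewing condition (main effects and all
#' interactions) with age and BCVA as covariates and a participant random
#' intercept. Because the residuals of such models typically violate
#' normality (checked here with a Shapiro-Wilk test), confidence intervals
#' are obtained by bootstrap: a parametric bootstrap at the fitted model by
#' default, or a participant-level (cluster) resampling bootstrap
#' (`type = "cluster"`), with percentile or basic intervals.
#'
#' @param table Main-sequence table from [main_sequence_table()]. A
#'   `group` or `viewing` column with a single level is dropped from the
#'   formula (with its interactions).
#' @param n_bootstrap Bootstrap replications (default 5000).
#' @param type `"parametric"` (default) or `"cluster"`.
#' @param ci_method `"percentile"` (default) or `"basic"`.
#' @param seed Integer seed for the bootstrap (logged in the result).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `main_sequence_fit`: the `lmerMod` fit, the
#'   fixed-effect table with bootstrap CIs, Shapiro-Wilk statistics, and
#'   the bootstrap settings.
#' @export
fit_main_sequence <- function(table, n_bootstrap = 5000,
                              type = c("parametric", "cluster"),
                              ci_method = c("percentile", "basic"),
                              seed = 1L, conf = 0.95) {
  type <- match.arg(type)
  ci_method <- match.arg(ci_method)
  tab <- table[table$complete %||% TRUE, , drop = FALSE]
  tab$group <- droplevels(as.factor(tab$group))
  if ("control" %in% levels(tab$group))
    tab$group <- stats::relevel(tab$group, ref = "control")
  tab$viewing <- droplevels(as.factor(tab$viewing))
  if ("binocular" %in% levels(tab$viewing))
    tab$viewing <- stats::relevel(tab$viewing, ref = "binocular")
  terms <- "amplitude_centered"
  if (nlevels(tab$group) > 1) terms <- c(terms, "group")
  if (nlevels(tab$viewing) > 1) terms <- c(terms, "viewing")
  fixed <- paste(terms, collapse = " * ")
  covs <- NULL
  if (length(unique(tab$age)) > 1) covs <- c(covs, "age")
  if (length(unique(tab$bcva)) > 1) covs <- c(covs, "bcva")
  rhs <- paste(c(fixed, covs, "(1 | participant)"), collapse = " + ")
  form <- stats::as.formula(paste("peak_velocity_deg_s ~", rhs))
  fit <- lme4::lmer(form, data = tab, REML = TRUE)

  res <- stats::residuals(fit)
  sw_res <- if (length(res) > 5000) {
    old <- .Random.seed_save()
    set.seed(seed)
    s <- stats::shapiro.test(sample(res, 5000))
    .Random.seed_restore(old)
    s
  } else stats::shapiro.test(res)

  fe <- lme4::fixef(fit)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot_mat <- if (type == "parametric") {
    bs <- lme4::bootMer(fit, fixef_fun, nsim = n_bootstrap, type = "parametric",
                        use.u = FALSE)
    bs$t
  } else {
    cluster_bootstrap(fit, tab, form, n_bootstrap)
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(boot_mat, 2, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE))
  if (ci_method == "basic") {
    ci <- cbind(2 * fe - ci[, 2], 2 * fe - ci[, 1])
  }
  colnames(ci) <- c("ci_lower", "ci_upper")
  est <- data.frame(term = names(fe), estimate = unname(fe),
                    ci_lower = ci[, 1], ci_upper = ci[, 2],
                    significant = ci[, 1] > 0 | ci[, 2] < 0,
                    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  structure(list(fit = fit, estimates = est,
                 shapiro_W = unname(sw_res$statistic),
                 shapiro_p = sw_res$p.value,
                 normality_violated = sw_res$p.value < 0.05,
                 n_bootstrap = n_bootstrap, bootstrap_type = type,
                 ci_method = ci_method, seed = seed, conf = conf,
                 n_saccades = nrow(tab),
                 n_participants = length(unique(tab$participant))),
            class = "main_sequence_fit")
}

fixef_fun <- function(m) lme4::fixef(m)

#' Simulate a two-group main-sequence data set
#'
#' Generates saccade amplitude / peak-velocity data for a parameter-recovery
#' study: amplitudes uniform on `amp_range`, peak velocities linear in
#' amplitude around the grand mean amplitude,
#' `v = velocity_at_mean + slope * (A - mean(A)) + u_participant + noise`,
#' with a group-specific slope increment (`case_slope_increment`), an
#' optional viewing-condition slope increment, Gaussian participant random
#' intercepts and residual noise. The generating velocity at the mean
#' amplitude therefore equals `velocity_at_mean` exactly, whatever the
#' amplitude distribution.
#'
#' @param n_per_group Participants per group (default 30).
#' @param n_saccades Saccades per participant (default 100).
#' @param control_slope Reference-group main-sequence slope, deg/s/deg
#'   (default 14.2).
#' @param case_slope_increment Extra slope for the case group (default 4.4).
#' @param monocular_slope_increment Extra slope for monocular viewing
#'   (default 1.5); half of each group's participants are assigned to each
#'   viewing condition when `two_viewings` is TRUE.
#' @param velocity_at_mean Peak velocity at the grand mean amplitude, deg/s
#'   (default 237).
#' @param amp_range Amplitude range, deg (default `c(2, 20)`).
#' @param resid_sd Residual velocity noise SD, deg/s (default 20).
#' @param intercept_sd Participant random-intercept SD, deg/s (default 10).
#' @param two_viewings Include a monocular viewing condition (default TRUE).
#' @param seed Integer seed.
#' @return A main-sequence table (see [main_sequence_table()]) ready for
#'   [fit_main_sequence()], with attribute `generating` holding the true
#'   parameter values.
#' @export
simulate_main_sequence_data <- function(n_per_group = 30, n_saccades = 100,
                                        control_slope = 14.2,
                                        case_slope_increment = 4.4,
                                        monocular_slope_increment = 1.5,
                                        velocity_at_mean = 237,
                                        amp_range = c(2, 20),
                                        resid_sd = 20, intercept_sd = 10,
                                        two_viewings = TRUE, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2L * n_per_group
  ids <- sprintf("P%03d", seq_len(n))
  group <- rep(c("control", "case"), each = n_per_group)
  viewing <- if (two_viewings)
    rep(rep(c("binocular", "monocular"), length.out = n_per_group), 2)
  else rep("binocular", n)
  age <- round(stats::runif(n, 20, 75))
  bcva <- round(stats::rnorm(n, 0, 0.08), 2)
  u <- stats::rnorm(n, 0, intercept_sd)
  tab <- data.frame(
    participant = rep(ids, each = n_saccades),
    group = rep(group, each = n_saccades),
    viewing = rep(viewing, each = n_saccades),
    age = rep(age, each = n_saccades),
    bcva = rep(bcva, each = n_saccades),
    amplitude_deg = stats::runif(n * n_saccades, amp_range[1], amp_range[2]),
    stringsAsFactors = FALSE)
  slope <- control_slope +
    case_slope_increment * (tab$group == "case") +
    monocular_slope_increment * (tab$viewing == "monocular")
  amp_c <- tab$amplitude_deg - mean(tab$amplitude_deg)
  tab$peak_velocity_deg_s <- velocity_at_mean + slope * amp_c +
    rep(u, each = n_saccades) + stats::rnorm(nrow(tab), 0, resid_sd)
  tab$amplitude_centered <- amp_c
  tab$complete <- TRUE
  attr(tab, "generating") <- list(
    control_slope = control_slope,
    case_slope_increment = case_slope_increment,
    monocular_slope_increment = monocular_slope_increment,
    velocity_at_mean = velocity_at_mean,
    resid_sd = resid_sd, intercept_sd = intercept_sd)
  tab
}

cluster_bootstrap <- function(fit, tab, form, nsim) {
  ids <- unique(tab$participant)
  fe <- lme4::fixef(fit)
  out <- matrix(NA_real_, nsim, length(fe),
                dimnames = list(NULL, names(fe)))
  for (b in seq_len(nsim)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    dfb <- do.call(rbind, lapply(seq_along(pick), function(i) {
      d <- tab[tab$participant == pick[i], , drop = FALSE]
      d$participant <- paste0("bs", i)
      d
    }))
    m <- try(suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dfb, REML = TRUE))), silent = TRUE)
    if (!inherits(m, "try-error")) {
      fb <- lme4::fixef(m)
      out[b, names(fb)] <- fb
    }
  }
  out
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf(
    "Main-sequence mixed model: %d saccades, %d participants\n",
    x$n_saccades, x$n_participants))
  cat(sprintf("  %s bootstrap, %d reps, %s %.0f%% CIs (seed %d)\n",
              x$bootstrap_type, x$n_bootstrap, x$ci_method, 100 * x$conf,
              x$seed))
  cat(sprintf("  Shapiro-Wilk on residuals: W = %.2f, p = %.2g%s\n",
              x$shapiro_W, x$shapiro_p,
              if (x$normality_violated) " (normality violated)" else ""))
  est <- x$estimates
  est$estimate <- sprintf("%.2f", est$estimate)
  est$ci <- sprintf("(%.2f, %.2f)%s", x$estimates$ci_lower,
                    x$estimates$ci_upper,
                    ifelse(est$significant, " *", ""))
  print(est[, c("term", "estimate", "ci")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.main_sequence_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying lmer fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.main_sequence_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$term)
}
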