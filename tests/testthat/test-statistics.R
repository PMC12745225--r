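test_that("the group comparison recovers a known effect with covariates", {
  set.seed(51)
  n <- 20
  group <- rep(c("control", "case"), each = n / 2)
  age <- runif(n, 40, 70)
  bcva <- rnorm(n, 0, 0.1)
  y <- 1.0 * (group == "case") + 0.01 * age + rnorm(n, 0, 0.1)
  res <- compare_groups(y, factor(group, levels = c("control", "case")),
                        age, bcva, name = "toy")
  expect_equal(res$estimate, 1.0, tolerance = 0.1)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$age_estimate, 0.01, tolerance = 0.01)
})

test_that("degenerate designs are rejected with informative errors", {
  g <- factor(rep(c("a", "b"), each = 10))
  y <- rnorm(20)
  expect_error(compare_groups(y, g, age = rep(1, 20), bcva = rnorm(20)),
               "collinear|singular")
  expect_error(compare_groups(y[1:5], factor(c("a", "a", "a", "b", "b")),
                              1:5, 1:5 * 0.1),
               "fewer than 3")
  expect_error(compare_groups(y, g, c(NA, rnorm(19)), rnorm(20)), "complete")
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(52)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)
    q <- fdr_adjust(p)
    expect_equal(q, bh_stepup(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= 0))  # order-preserving
  }
})

test_that("Mann-Whitney demographic tests behave at the extremes", {
  expect_gt(demographic_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.9)
  sep <- demographic_test(1:10, 21:30)
  expect_equal(sep$U, 0)
  expect_lt(sep$p_value, 0.001)
  expect_error(demographic_test(numeric(0), 1:3), "empty")
})

test_that("null Mann-Whitney p-values reject at close to the nominal rate", {
  set.seed(53)
  rej <- mean(replicate(400, {
    demographic_test(rnorm(15), rnorm(15))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("a noiseless single-group main sequence is fit exactly", {
  tab <- data.frame(
    participant = rep(c("a", "b", "c"), each = 20),
    group = "control", viewing = "binocular", age = 50, bcva = 0,
    amplitude_deg = rep(seq(2, 20, length.out = 20), 3))
  tab$amplitude_centered <- tab$amplitude_deg - mean(tab$amplitude_deg)
  tab$peak_velocity_deg_s <- 237 + 14.2 * tab$amplitude_centered
  tab$complete <- TRUE
  # the exact fit is degenerate (zero residual variance), which trips lmer's
  # convergence heuristics without affecting the estimates
  fit <- suppressWarnings(suppressMessages(
    fit_main_sequence(tab, n_bootstrap = 10, seed = 2)))
  est <- fit$estimates
  expect_equal(est$estimate[est$term == "amplitude_centered"], 14.2,
               tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "(Intercept)"], 237,
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  expect_lt(vc$vcov[1], 1e-8)
})

test_that("heavy-tailed residuals raise the normality-violation flag", {
  set.seed(54)
  tab <- simulate_main_sequence_data(n_per_group = 5, n_saccades = 40,
                                     resid_sd = 1, seed = 7)
  tab$peak_velocity_deg_s <- tab$peak_velocity_deg_s + 20 * rt(nrow(tab), df = 2)
  fit <- fit_main_sequence(tab, n_bootstrap = 10, seed = 3)
  expect_lt(fit$shapiro_p, 0.05)
  expect_true(fit$normality_violated)
  expect_lt(fit$shapiro_W, 0.99)
})

test_that("the mixed model recovers generating parameters within bootstrap CIs", {
  tab <- simulate_main_sequence_data(n_per_group = 10, n_saccades = 40,
                                     seed = 8)
  gen <- attr(tab, "generating")
  fit <- fit_main_sequence(tab, n_bootstrap = 200, seed = 4)
  est <- fit$estimates
  pick <- function(term) est[est$term == term, ]
  sl <- pick("amplitude_centered")
  expect_gt(gen$control_slope, sl$ci_lower)
  expect_lt(gen$control_slope, sl$ci_upper)
  inter <- pick("amplitude_centered:groupcase")
  expect_gt(gen$case_slope_increment, inter$ci_lower)
  expect_lt(gen$case_slope_increment, inter$ci_upper)
  expect_equal(sl$estimate, gen$control_slope, tolerance = 0.05 * gen$control_slope)
  # CI defines significance
  expect_true(sl$significant)
})

test_that("the cluster bootstrap variant also produces usable intervals", {
  tab <- simulate_main_sequence_data(n_per_group = 6, n_saccades = 25,
                                     two_viewings = FALSE, seed = 9)
  fit <- fit_main_sequence(tab, n_bootstrap = 30, type = "cluster", seed = 5)
  est <- fit$estimates
  sl <- est[est$term == "amplitude_centered", ]
  expect_true(sl$ci_lower < sl$estimate && sl$estimate < sl$ci_upper)
  expect_equal(sl$estimate, 14.2, tolerance = 1)
})

test_that("bootstrap CI width shrinks with the cohort size", {
  w <- vapply(c(5, 20), function(np) {
    tab <- simulate_main_sequence_data(n_per_group = np, n_saccades = 30,
                                       two_viewings = FALSE, seed = 11)
    fit <- fit_main_sequence(tab, n_bootstrap = 100, seed = 6)
    est <- fit$estimates
    sl <- est[est$term == "amplitude_centered", ]
    sl$ci_upper - sl$ci_lower
  }, numeric(1))
  expect_lt(w[2], w[1])
})
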