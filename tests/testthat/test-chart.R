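# Shared Phase-I fixture: one simulated trial, control-arm fit.
chart_fixture <- local({
  co <- simulate_cohort(sim_config(seed = 501))
  ctrl <- co[co$arm == "control", ]
  list(cohort = co, ctrl = ctrl,
       fit = fit_cox(ctrl, c("ecog", "eod", "pi")))
})

test_that("EWMA smoothing satisfies its recursion identities", {
  cfg1 <- chart_config(lambda = 1)
  u <- c(0.3, -1.2, 0.8)
  expect_equal(ewma_smooth(u, cfg1), u)            # lambda = 1: no smoothing

  cfg <- chart_config(lambda = 0.2, z0 = 0)
  expect_equal(ewma_smooth(c(1, 1, 1), cfg), c(0.2, 0.36, 0.488))
  expect_length(ewma_smooth(numeric(0), cfg), 0)

  # constant input: monotone approach to the fixed point
  z <- ewma_smooth(rep(2, 50), cfg)
  expect_true(all(diff(z) > 0))
  expect_equal(z[50], 2, tolerance = 1e-4)

  # recursion identity holds exactly for an arbitrary series
  set.seed(101)
  u <- stats::rnorm(40)
  z <- ewma_smooth(u, cfg)
  expect_equal(z, 0.2 * u + 0.8 * c(0, z[-40]))
})

test_that("case scores follow the standardized martingale conventions", {
  fit <- chart_fixture$fit
  cfg <- chart_config()
  first_event <- min(fit$baseline$times)
  rec <- chart_fixture$ctrl[1:2, ]
  rec$time <- first_event / 2
  rec$event <- 0L
  expect_equal(case_scores(rec, fit, cfg), c(0, 0))  # censored before support

  # an event with expected count exactly 1 scores 0
  rec2 <- chart_fixture$ctrl[3, ]
  lp <- predict(fit, rec2, type = "risk")
  target_t <- raes:::cumhaz_invert(fit$baseline, 1 / lp)
  if (!is.na(target_t)) {
    rec2$time <- target_t
    rec2$event <- 1L
    H <- predict(fit, rec2, type = "expected")
    expect_equal(case_scores(rec2, fit, cfg),
                 (1 - H) / sqrt(H))
  }

  # beyond-support times warn and reuse the last baseline value
  rec3 <- chart_fixture$ctrl[4, ]
  rec3$time <- max(fit$baseline$times) * 2
  expect_warning(case_scores(rec3, fit, cfg), "support")

  # scores of the monitored set are invariant to padding the Phase-I
  # training data with censored-at-zero control patients
  padded <- chart_fixture$ctrl
  pad <- padded[1:5, ]
  pad$id <- paste0("pad", 1:5)
  pad$time <- 1e-6
  pad$event <- 0L
  fit_pad <- fit_cox(rbind(padded, pad), c("ecog", "eod", "pi"))
  test_arm <- chart_fixture$cohort[chart_fixture$cohort$arm == "treatment", ]
  expect_equal(suppressWarnings(case_scores(test_arm, fit_pad, cfg)),
               suppressWarnings(case_scores(test_arm, fit, cfg)),
               tolerance = 1e-6)

  # the in-control score mean is positive by construction (the
  # standardizing weight correlates with the residual); for fully
  # observed cases it approaches E[(1-E)/sqrt(E)] = sqrt(pi)/2 with
  # E ~ Exp(1), pulled down by support-truncated (censored) draws
  arm <- simulate_null_arm(fit, chart_fixture$ctrl, 10000, seed = 502)
  mu <- mean(case_scores(arm, fit, cfg))
  expect_gt(mu, 0.4)
  expect_lt(mu, sqrt(pi) / 2 + 0.05)
})

test_that("limit calibration rejects impossible targets and nests by alpha", {
  fit <- chart_fixture$fit
  expect_error(chart_config(alpha = 0), "alpha")
  expect_error(chart_config(calibration_reps = 50), "calibration_reps")

  cfg5 <- chart_config(alpha = 0.05, calibration_reps = 150, seed = 503)
  cfg05 <- chart_config(alpha = 0.005, calibration_reps = 150, seed = 503)
  lim5 <- calibrate_limits(fit, chart_fixture$ctrl, 60, cfg5)
  lim05 <- calibrate_limits(fit, chart_fixture$ctrl, 60, cfg05)
  tt <- 1:60
  expect_true(all(lim5$upper(tt) < lim05$upper(tt)))
  expect_true(all(lim5$lower(tt) > lim05$lower(tt)))
  expect_true(all(lim5$upper(tt) > lim5$lower(tt)))
  # limit half-width widens with t (EWMA variance inflation)
  hw <- lim05$upper(tt) - lim05$lower(tt)
  expect_true(all(diff(hw) > 0))
  # the centerline tracks the in-control score mean on fresh draws
  arm <- simulate_null_arm(chart_fixture$fit, chart_fixture$ctrl, 8000,
                           seed = 520)
  expect_equal(mean(case_scores(arm, chart_fixture$fit, cfg05)),
               lim05$mu_U, tolerance = 0.08)
})

test_that("monitoring flags crossings consistently and handles empty input", {
  fit <- chart_fixture$fit
  cfg <- chart_config(calibration_reps = 150, seed = 504)
  lim <- calibrate_limits(fit, chart_fixture$ctrl, 100, cfg)

  empty <- chart_fixture$ctrl[0, ]
  ch0 <- monitor_sequence(empty, fit, lim, cfg)
  expect_equal(nrow(ch0$series), 0)

  arm <- simulate_null_arm(fit, chart_fixture$ctrl, 100, seed = 505)
  ch <- monitor_sequence(arm, fit, lim, cfg)
  s <- ch$series
  expect_equal(s$Z, ewma_smooth(s$U, cfg))
  expect_equal(which(s$Z < s$lower), ch$signal_low)
  expect_equal(which(s$Z > s$upper), ch$signal_high)
  expect_identical(s$signal_low, s$Z < s$lower)

  # a strongly improved arm triggers low-side signals
  improved <- fit
  improved$baseline <- step_hazard(fit$baseline$times,
                                   fit$baseline$increments * 0.3)
  arm2 <- simulate_null_arm(improved, chart_fixture$ctrl, 100, seed = 506)
  ch2 <- monitor_sequence(arm2, fit, lim, cfg)
  expect_gt(length(ch2$signal_low), 0)
})

test_that("operating characteristics are null-centered and monotone in the shift", {
  fit <- chart_fixture$fit
  cfg <- chart_config(calibration_reps = 150, seed = 507)
  lim <- calibrate_limits(fit, chart_fixture$ctrl, 80, cfg)
  expect_error(oc_study(fit, chart_fixture$ctrl, numeric(0), cfg, lim),
               "non-empty")
  oc <- oc_study(fit, chart_fixture$ctrl, c(0, -0.4, -0.8), cfg,
                 limits = lim, reps = 60)
  expect_equal(nrow(oc), 3)
  # null row near alpha (generous Monte-Carlo tolerance at these reps)
  expect_lt(oc$low_rate[1] + oc$high_rate[1], 10 * cfg$alpha)
  # low-side rate nondecreasing as the shift decreases below 0
  expect_true(oc$low_rate[3] >= oc$low_rate[2] - 2 * oc$low_se[2])
  expect_gt(oc$low_rate[3], oc$low_rate[1])

  oc1 <- oc_study(fit, chart_fixture$ctrl, -0.5, cfg, limits = lim, reps = 30)
  expect_equal(nrow(oc1), 1)
})
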