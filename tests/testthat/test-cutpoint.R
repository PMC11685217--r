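test_that("the maximally selected cut-point equals exhaustive search, including ties", {
  expect_error(max_logrank_cutpoint(
    trial_cohort(transform(make_cohort_df(20, 1), mk = 5)), "mk"), "constant")

  for (r in 1:12) {
    co <- make_cohort(n = 45, seed = 300 + r)
    cp <- max_logrank_cutpoint(co, "mk", minprop = 0.1)
    bf <- brute_force_cutpoint(co, "mk", minprop = 0.1)
    expect_identical(cp$cutpoint, bf$cutpoint)
    expect_equal(cp$abs_statistic, bf$abs_statistic, tolerance = 1e-9)
    # the selected statistic is the max of the profile
    expect_equal(cp$abs_statistic, max(abs(cp$profile$z)))
    # the cut-point is an observed value inside the inner quantile band
    expect_true(cp$cutpoint %in% co$mk)
    expect_gte(mean(co$mk <= cp$cutpoint), 0.1)
    expect_gte(mean(co$mk > cp$cutpoint), 0.1)
  }
})

test_that("dichotomization uses a strict 'greater than' boundary", {
  co <- make_cohort(n = 40, seed = 310)
  cp <- max_logrank_cutpoint(co, "mk")$cutpoint
  hi_at <- co$mk > cp
  nxt <- min(co$mk[co$mk > cp])
  hi_next <- co$mk > nxt
  # moving the threshold to the next observed value reclassifies exactly
  # the patients sitting at that next value
  expect_identical(which(hi_at & !hi_next), which(co$mk == nxt))
})

test_that("threshold-effect cut-points are recovered near the true quantile", {
  # a prognostic threshold effect carried by every patient: put the
  # whole n = 400 cohort on the effect side of the generator
  hits <- vapply(1:40, function(r) {
    cfg <- sim_config(n_control = 0, n_treatment = 400,
                      markers = list(mk = c(meanlog = 8, sdlog = 1)),
                      interactions = list(list(marker = "mk", quantile = 0.4,
                                               loghr = -0.7)),
                      treatment_loghr = 0, seed = 400 + r)
    co <- simulate_cohort(cfg)
    cp <- max_logrank_cutpoint(co, "mk")
    abs(mean(co$mk <= cp$cutpoint) - 0.4) <= 0.10
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("the interaction model reports coherent subgroup contrasts", {
  cfg <- sim_config(markers = list(mk = c(meanlog = 8, sdlog = 1)),
                    interactions = list(list(marker = "mk", quantile = 0.5,
                                             loghr = -0.8)),
                    seed = 320)
  co <- simulate_cohort(cfg)
  cut <- attr(co, "truth")$mk
  ir <- interaction_cox(co, "mk", cut)
  expect_s3_class(ir, "interaction_result")
  expect_lt(ir$p, 0.05)
  expect_true(ir$ci[1] < ir$interaction_hr & ir$interaction_hr < ir$ci[2])
  # benefit lives in the high class: treatment HR below the low class's
  expect_lt(ir$subgroup$high$hr, ir$subgroup$low$hr)

  # all markers on one side of the cut is an error
  expect_error(interaction_cox(co, "mk", max(co$mk) + 1), "empty cell")

  # constraining the interaction to zero reproduces the main-effects
  # likelihood (nesting)
  df <- as.data.frame(co)
  df$.high <- as.numeric(df$mk > cut)
  df$.inter <- as.numeric(df$arm == "treatment") * df$.high
  main <- fit_cox(df, c("treatment", ".high", "ecog", "eod", "pi"))
  ll_constrained <- raes:::cox_loglik(
    df, c("treatment", ".high", ".inter", "ecog", "eod", "pi"),
    c(coef(main)[c("treatment", ".high")], .inter = 0,
      coef(main)[c("ecog", "eod", "pi")]))
  expect_equal(ll_constrained, main$loglik, tolerance = 1e-10)
})

test_that("bootstrap stability is deterministic and detects strong interactions", {
  cfg <- sim_config(markers = list(mk = c(meanlog = 8, sdlog = 1)),
                    interactions = list(list(marker = "mk", quantile = 0.5,
                                             loghr = -0.7)),
                    seed = 330)
  co <- simulate_cohort(cfg)
  cut <- attr(co, "truth")$mk
  expect_error(bootstrap_cutpoint_stability(co, "mk", cut, B = 0, seed = 1),
               "B must")
  b1 <- bootstrap_cutpoint_stability(co, "mk", cut, B = 40, seed = 331)
  b2 <- bootstrap_cutpoint_stability(co, "mk", cut, B = 40, seed = 331)
  expect_identical(b1, b2)
  expect_true(b1$proportion >= 0 && b1$proportion <= 1)
  expect_equal(b1$n_used + b1$n_skipped, 40L)
})

test_that("subgroup charts require enough control-arm events and find confined benefit", {
  cfg <- sim_config(markers = list(mk = c(meanlog = 8, sdlog = 1)), seed = 340)
  co <- simulate_cohort(cfg)
  expect_error(
    subgroup_charts(co, "mk", stats::quantile(co$mk, 0.98),
                    chart_config(calibration_reps = 100, seed = 1)),
    "subgroup 'high'")

  # benefit confined to the high class: more low-side signals there
  rates <- vapply(1:12, function(r) {
    cfg <- sim_config(markers = list(mk = c(meanlog = 8, sdlog = 1)),
                      interactions = list(list(marker = "mk", quantile = 0.5,
                                               loghr = -0.9)),
                      treatment_loghr = 0, seed = 3400 + r)
    co <- simulate_cohort(cfg)
    sc <- suppressWarnings(
      subgroup_charts(co, "mk", attr(co, "truth")$mk,
                      chart_config(calibration_reps = 100, seed = 3500 + r)))
    c(high = summary(sc$high)$n_signal_low / summary(sc$high)$n,
      low = summary(sc$low)$n_signal_low / summary(sc$low)$n)
  }, c(high = 0, low = 0))
  expect_gt(mean(rates["high", ]), mean(rates["low", ]))
})
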