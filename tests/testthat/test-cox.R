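test_that("the partial-likelihood solver matches an independent reference on random cohorts", {
  # oracle equivalence: survival::coxph on 20 random small cohorts, both
  # ties methods, coefficients to 4 decimals (we check much tighter)
  for (r in 1:20) {
    d <- make_surv_df(n = 50 + 5 * r, seed = 100 + r, p = 2,
                      beta = c(0.5, -0.3), cens_rate = 0.3)
    d$time <- round(d$time, 1) + 0.01          # induce ties
    for (ties in c("efron", "breslow")) {
      fit <- fit_cox(d, c("x1", "x2"), ties = ties)
      ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                             data = d, ties = ties)
      expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(vcov(fit)), unname(vcov(ref)), tolerance = 1e-6)
      expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
    }
  }
})

test_that("degenerate designs are rejected with informative errors", {
  d <- make_surv_df(n = 30, seed = 7)
  d$flat <- 1
  expect_error(fit_cox(d, c("x1", "flat")), "flat")
  d0 <- d
  d0$event <- 0
  expect_error(fit_cox(d0, "x1"), "event")
  d$x3 <- d$x1                                  # exact collinearity
  expect_error(fit_cox(d, c("x1", "x3")), "singular|collinear")
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta = 0 and matches hand risk sets", {
  # property: with a single centered covariate forced to effect ~0 the
  # baseline increments are d_j/n_j
  for (r in 1:5) {
    d <- make_surv_df(n = 40, seed = 200 + r, p = 1, beta = 0.4,
                      cens_rate = 0.3)
    d$time <- round(d$time, 1) + 0.01            # ties too
    ord <- order(d$time)
    ts <- d$time[ord]; ss <- d$event[ord]
    ut <- unique(ts)
    dj <- rowsum(ss, match(ts, ut))[, 1]
    cj <- rowsum(rep(1, length(ts)), match(ts, ut))[, 1]
    nj <- rev(cumsum(rev(cj)))
    na <- cumsum((dj / nj)[dj > 0])
    bl0 <- raes:::cox_breslow_at(d$time, d$event, cbind(x1 = d$x1), 0)
    expect_equal(unname(bl0$cumhaz), unname(na), tolerance = 1e-12)
  }

  # 3 subjects, x = (0,1,0), first event from the x = 1 subject at
  # beta = log 2: increment 1/(2 + 1 + 1) = 0.25
  d3 <- data.frame(time = c(2, 1, 3), event = c(1, 1, 1), x = c(0, 1, 0))
  bl <- raes:::cox_breslow_at(d3$time, d3$event, cbind(x = d3$x), log(2))
  expect_equal(bl$increments[1], 0.25)

  # single subject with an event: Lambda0 at its time is 1
  b1 <- raes:::cox_breslow_at(5, 1, cbind(x = 0), 0.7)
  expect_equal(b1$cumhaz, 1)
})

test_that("martingale residuals satisfy the estimating-equation identity", {
  d <- make_surv_df(n = 200, seed = 55, p = 2, beta = c(0.6, -0.4),
                    cens_rate = 0.2)
  d$time <- round(d$time, 1) + 0.01              # ties exercise Efron
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(d, c("x1", "x2"), ties = ties)
    m <- martingale_residuals(fit)
    expect_lt(abs(sum(m)), 1e-6)
    expect_true(all(m <= 1))
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                           data = d, ties = ties)
    expect_equal(m, unname(stats::resid(ref, type = "martingale")),
                 tolerance = 1e-6)
  }

  # censored before the first event time: residual 0
  fit <- fit_cox(d, c("x1", "x2"))
  new <- data.frame(time = min(d$time[d$event == 1]) / 2, event = 0,
                    x1 = 1, x2 = -1)
  expect_equal(martingale_residuals(fit, new), 0)
})

test_that("recovered coefficients and Wald inference behave at moderate n", {
  d <- make_surv_df(n = 500, seed = 60, p = 2, beta = c(0.7, -0.65),
                    cens_rate = 0.25)
  fit <- fit_cox(d, c("x1", "x2"))
  expect_lt(max(abs(coef(fit) - c(0.7, -0.65))), 0.15)
  s <- summary(fit)
  expect_true(all(s$hr_low < s$hr & s$hr < s$hr_high))
})

test_that("the proportional-hazards diagnostic tracks cox.zph and detects violations", {
  d <- make_surv_df(n = 300, seed = 70, p = 2, beta = c(0.5, 0),
                    cens_rate = 0.2)
  fit <- fit_cox(d, c("x1", "x2"))
  mine <- schoenfeld_ph_test(fit, transform = "km")
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d),
    transform = "km")$table
  expect_equal(mine$p[1:2], unname(ref[1:2, "p"]), tolerance = 0.15)

  # strong sign-crossing time-varying effect: piecewise hazard where the
  # covariate helps early and harms late
  set.seed(71)
  n <- 500
  x <- stats::rnorm(n)
  t0 <- 1
  # piecewise exponential: rate exp(+x) before t0, exp(-x) after
  t1 <- stats::rexp(n, exp(x))
  tt <- ifelse(t1 < t0, t1, t0 + stats::rexp(n, exp(-x)))
  dtv <- data.frame(time = tt, event = 1, x = x)
  ftv <- fit_cox(dtv, "x")
  expect_lt(schoenfeld_ph_test(ftv)$p[1], 0.05)

  # one event only (a symmetric design that converges at beta = 0)
  d1 <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0), x1 = c(0, 1, -1))
  f1 <- fit_cox(d1, "x1")
  expect_error(schoenfeld_ph_test(f1), "2 events")
})

test_that("predictions expose lp, risk, expected counts and survival consistently", {
  d <- make_surv_df(n = 100, seed = 80, p = 2, beta = c(0.4, 0.2))
  fit <- fit_cox(d, c("x1", "x2"))
  lp <- predict(fit, type = "lp")
  expect_equal(predict(fit, type = "risk"), exp(lp))
  ex <- predict(fit, type = "expected")
  expect_equal(predict(fit, type = "survival"), exp(-ex))
  expect_equal(d$event - ex, martingale_residuals(fit, d))
  expect_error(predict(fit, newdata = data.frame(time = 1)), "unknown covariate")
})
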