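#' Fit a Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with
#' step-halving (gradient tolerance `1e-8`, at most 100 iterations),
#' with Efron (default) or Breslow handling of tied event times, and
#' returns the fitted log-hazard ratios together with the Breslow
#' baseline cumulative hazard step function estimated at the fitted
#' coefficients. Covariates are centered internally for numerical
#' stability; the reported baseline refers to covariates equal to zero.
#'
#' @param cohort a [trial_cohort()] or data.frame with `time` and `event`
#'   columns and the covariate columns.
#' @param covariates character vector of covariate names. The special
#'   name `"treatment"` expands to the indicator `arm == "treatment"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the max absolute score component.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `cox_fit`: a list with elements
#'   `coefficients` (named log-hazard ratios), `var` (covariance matrix),
#'   `baseline` (a `step_hazard`), `loglik`, `loglik_null`, `n`,
#'   `n_events`, `ties`, plus the data needed by the residual and
#'   prediction methods. `exp(coef)` are hazard ratios; Wald 95%
#'   confidence intervals are `exp(coef +/- 1.96 * se)` (see
#'   [summary.cox_fit()]).
#' @examples
#' co <- simulate_cohort(sim_config(seed = 1))
#' fit <- fit_cox(co[co$arm == "control", ], c("ecog", "eod", "pi"))
#' summary(fit)
#' @export
fit_cox <- function(cohort, covariates, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 100L) {
  ties <- match.arg(ties)
  X <- cox_design(cohort, covariates)
  cf <- cox_engine(cohort$time, cohort$event, X, ties = ties,
                   tol = tol, max_iter = max_iter)
  cf$call <- match.call()
  cf
}

# Build the design matrix from named cohort columns; "treatment" expands
# to the arm indicator.
cox_design <- function(cohort, covariates) {
  n <- nrow(cohort)
  X <- matrix(0, n, length(covariates),
              dimnames = list(NULL, covariates))
  for (v in covariates) {
    X[, v] <- if (v == "treatment") {
      if (!"arm" %in% names(cohort))
        stop_("covariate 'treatment' requires an 'arm' column")
      as.numeric(cohort$arm == "treatment")
    } else {
      if (!v %in% names(cohort)) stop_("unknown covariate '%s'", v)
      as.numeric(cohort[[v]])
    }
  }
  X
}

# Partial likelihood, score and information at beta, on data sorted by
# increasing time. Tied event times are expanded into per-(time, l)
# pseudo-terms: Efron subtracts the fraction l/d of the tied deaths'
# risk weight, Breslow subtracts nothing, which makes both methods one
# vectorized computation.
cox_eval <- function(beta, ts, ss, Xs, grp, gstart, d, ii, jj, efron) {
  n <- length(ts)
  p <- ncol(Xs)
  eta <- drop(Xs %*% beta)
  w <- exp(eta)
  WX <- w * Xs
  WXX <- w * (Xs[, ii, drop = FALSE] * Xs[, jj, drop = FALSE])
  rc0 <- revcumsum(w)
  rc1 <- revcumsum(WX)
  rc2 <- revcumsum(WXX)

  egi <- which(d > 0L)                       # distinct event times
  reps <- d[egi]
  gi <- rep.int(egi, reps)
  f <- if (efron) unlist(lapply(reps, function(k) (seq_len(k) - 1) / k))
       else rep.int(0, sum(reps))

  st <- gstart[gi]
  D0 <- rowsum(ss * w, grp)
  D1 <- rowsum(ss * WX, grp)
  D2 <- rowsum(ss * WXX, grp)

  PHI0 <- rc0[st] - f * D0[gi]
  PHI1 <- rc1[st, , drop = FALSE] - f * D1[gi, , drop = FALSE]
  PHI2 <- rc2[st, , drop = FALSE] - f * D2[gi, , drop = FALSE]
  if (any(PHI0 <= 0)) stop_("empty or degenerate risk set")

  loglik <- sum(ss * eta) - sum(log(PHI0))
  A <- PHI1 / PHI0
  grad <- colSums(ss * Xs) - colSums(A)
  ipack <- colSums(PHI2 / PHI0) - colSums(A[, ii, drop = FALSE] * A[, jj, drop = FALSE])
  info <- matrix(0, p, p)
  info[cbind(ii, jj)] <- ipack
  info[cbind(jj, ii)] <- ipack

  # Baseline increments d_j/S0_j (Breslow) or sum_l 1/phi_jl (Efron),
  # and the Efron correction term sum_l (l/d)/phi_jl used by the
  # training-data martingale residuals.
  inc <- rowsum(1 / PHI0, gi)[, 1L]
  corr <- rowsum(f / PHI0, gi)[, 1L]
  list(loglik = loglik, grad = grad, info = info,
       inc = inc, corr = corr, egi = egi, w = w)
}

cox_engine <- function(time, status, X, ties = "efron",
                       tol = 1e-8, max_iter = 100L) {
  n <- length(time)
  p <- ncol(X)
  if (n < 2L) stop_("need at least two observations")
  if (sum(status) < 1) stop_("need at least one event")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop_("constant covariate(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))

  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)

  ord <- order(time)
  ts <- time[ord]; ss <- status[ord]
  Xs <- Xc[ord, , drop = FALSE]
  newgrp <- !duplicated(ts)
  grp <- cumsum(newgrp)
  gstart <- which(newgrp)
  d <- rowsum(ss, grp)[, 1L]
  lower <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  ii <- lower[, 1L]; jj <- lower[, 2L]
  efron <- ties == "efron"

  beta <- rep(0, p)
  ev <- cox_eval(beta, ts, ss, Xs, grp, gstart, d, ii, jj, efron)
  loglik_null <- ev$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(ev$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e)
      stop_("singular information matrix (exact collinearity among covariates?)"))
    new_beta <- beta + step
    new_ev <- cox_eval(new_beta, ts, ss, Xs, grp, gstart, d, ii, jj, efron)
    h <- 0L
    while (new_ev$loglik < ev$loglik - 1e-12 && h < 25L) {
      step <- step / 2
      new_beta <- beta + step
      new_ev <- cox_eval(new_beta, ts, ss, Xs, grp, gstart, d, ii, jj, efron)
      h <- h + 1L
    }
    beta <- new_beta; ev <- new_ev
    if (any(abs(beta) > 25))
      stop_("divergent coefficients (monotone likelihood?): |beta| > 25 for %s",
            paste(colnames(X)[abs(beta) > 25], collapse = ", "))
  }
  if (!converged && max(abs(ev$grad)) >= tol)
    stop_("Newton-Raphson failed to converge in %d iterations (score norm %.3g)",
          max_iter, max(abs(ev$grad)))

  var <- solve(ev$info)
  dimnames(var) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  # Baseline for covariates at zero: the centered fit's baseline refers
  # to x = colMeans(X), so rescale the increments.
  scale0 <- exp(-sum(beta * ctr))
  inc0 <- ev$inc * scale0
  bl <- step_hazard(ts[gstart[ev$egi]], inc0)

  structure(list(
    coefficients = beta, var = var, baseline = bl,
    loglik = ev$loglik, loglik_null = loglik_null,
    n = n, n_events = sum(status), ties = ties,
    iterations = it, center = ctr,
    time = time, status = status, X = X,
    efron_corr = ev$corr * scale0, event_group = ev$egi,
    sorted = list(ord = ord, grp = grp, gstart = gstart, d = d)
  ), class = "cox_fit")
}

# Breslow baseline evaluated at a fixed coefficient vector, no fitting
# and no centering (the baseline refers to x = 0 directly). At beta = 0
# this is exactly the Nelson-Aalen estimator.
cox_breslow_at <- function(time, status, X, beta, ties = "breslow") {
  X <- as.matrix(X)
  ord <- order(time)
  ts <- time[ord]; ss <- status[ord]
  Xs <- X[ord, , drop = FALSE]
  newgrp <- !duplicated(ts)
  grp <- cumsum(newgrp); gstart <- which(newgrp)
  d <- rowsum(ss, grp)[, 1L]
  p <- ncol(X)
  lower <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  ev <- cox_eval(as.numeric(beta), ts, ss, Xs, grp, gstart, d,
                 lower[, 1L], lower[, 2L], ties == "efron")
  step_hazard(ts[gstart[ev$egi]], ev$inc)
}

# Evaluate the partial log-likelihood of a fitted design at an arbitrary
# beta (used for nested-model likelihood checks).
cox_loglik <- function(cohort, covariates, beta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- cox_design(cohort, covariates)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ord <- order(cohort$time)
  ts <- cohort$time[ord]; ss <- cohort$event[ord]
  Xs <- Xc[ord, , drop = FALSE]
  newgrp <- !duplicated(ts)
  grp <- cumsum(newgrp); gstart <- which(newgrp)
  d <- rowsum(ss, grp)[, 1L]
  p <- ncol(X)
  lower <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cox_eval(beta, ts, ss, Xs, grp, gstart, d, lower[, 1L], lower[, 2L],
           ties == "efron")$loglik
}

#' Baseline cumulative hazard step function
#'
#' Right-continuous nondecreasing step function with `H(t) = 0` before
#' the first event time. Increments at event time `t_j` are
#' `d_j / sum_{i in R(t_j)} exp(beta' x_i)` (Breslow; the Efron variant
#' spreads tied deaths over the risk-set denominators).
#'
#' @param times strictly increasing event times.
#' @param increments positive hazard increments, one per time.
#' @return object of class `step_hazard`.
#' @export
step_hazard <- function(times, increments) {
  times <- unname(times)
  increments <- unname(increments)
  if (length(times) != length(increments))
    stop_("times and increments must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop_("event times must be strictly increasing")
  if (any(increments < 0)) stop_("hazard increments must be nonnegative")
  structure(list(times = times, increments = increments,
                 cumhaz = cumsum(increments)),
            class = "step_hazard")
}

#' Evaluate a baseline cumulative hazard at arbitrary times
#' @param hazard a [step_hazard()].
#' @param t numeric vector of times.
#' @return `H(t)`, flat at the last value beyond the support.
#' @export
cumhaz_at <- function(hazard, t) {
  idx <- findInterval(t, hazard$times)
  unname(c(0, hazard$cumhaz)[idx + 1L])
}

# Piecewise-constant inversion: smallest event time whose cumulative
# hazard reaches the target; NA if the target exceeds the support.
cumhaz_invert <- function(hazard, target) {
  k <- length(hazard$cumhaz)
  pos <- findInterval(target, hazard$cumhaz, left.open = TRUE) + 1L
  out <- rep(NA_real_, length(target))
  ok <- pos <= k
  out[ok] <- hazard$times[pos[ok]]
  out
}

#' Breslow baseline cumulative hazard of a fitted model
#' @param fit a [fit_cox()] object.
#' @return the `step_hazard` baseline (covariates at zero).
#' @export
breslow_cumhaz <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  fit$baseline
}

#' Martingale residuals under a fitted Cox model
#'
#' `M_i = delta_i - H0(t_i) * exp(beta' x_i)`: the observed minus
#' expected event count for patient `i`. On the training data the
#' residuals sum to zero (an estimating-equation identity, for either
#' ties method); for new records the expected count uses the fitted
#' baseline directly.
#'
#' @param fit a [fit_cox()] object.
#' @param newdata optional data.frame of new records carrying the fit's
#'   covariates plus `time` and `event`; default: the training data.
#' @return numeric vector of residuals (each at most 1).
#' @export
martingale_residuals <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(newdata)) {
    w <- exp(drop(fit$X %*% fit$coefficients))
    expected <- w * cumhaz_at(fit$baseline, fit$time)
    if (fit$ties == "efron") {
      # deaths inside a tied group see the downweighted denominators
      ord <- fit$sorted$ord
      grp_of <- fit$sorted$grp
      corr_full <- numeric(max(grp_of))
      corr_full[fit$event_group] <- fit$efron_corr
      adj <- numeric(fit$n)
      adj[ord] <- fit$status[ord] * corr_full[grp_of]
      expected <- expected - w * adj
    }
    fit$status - expected
  } else {
    X <- cox_design(newdata, names(fit$coefficients))
    w <- exp(drop(X %*% fit$coefficients))
    newdata$event - w * cumhaz_at(fit$baseline, newdata$time)
  }
}

#' @export
residuals.cox_fit <- function(object, type = c("martingale"), ...) {
  type <- match.arg(type)
  martingale_residuals(object)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Predictions from a fitted Cox model
#'
#' @param object a [fit_cox()] object.
#' @param newdata data.frame with the fit's covariates (and `time` for
#'   `type = "expected"` or `"survival"`); default: training data.
#' @param type `"lp"` (linear predictor), `"risk"` (`exp(lp)`),
#'   `"expected"` (`H0(t) exp(lp)`, the expected event count by the
#'   record's follow-up time) or `"survival"` (`exp(-expected)`).
#' @param ... unused.
#' @export
predict.cox_fit <- function(object, newdata = NULL,
                            type = c("lp", "risk", "expected", "survival"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
    tt <- object$time
  } else {
    X <- cox_design(newdata, names(object$coefficients))
    tt <- newdata$time
  }
  lp <- drop(X %*% object$coefficients)
  switch(type,
         lp = lp,
         risk = exp(lp),
         expected = exp(lp) * cumhaz_at(object$baseline, tt),
         survival = exp(-exp(lp) * cumhaz_at(object$baseline, tt)))
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  se <- sqrt(diag(x$var))
  tab <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               se = se, z = x$coefficients / se,
               p = 2 * stats::pnorm(-abs(x$coefficients / se)))
  print(round(tab, digits))
  invisible(x)
}

#' Summary of a Cox fit, in hazard-ratio form
#'
#' @param object a [fit_cox()] object.
#' @param bh apply Benjamini-Hochberg adjustment across the model's
#'   covariate p-values (default `FALSE`).
#' @param ... unused.
#' @return data.frame with HR, 95% CI bounds, p (and `p_adj` if `bh`).
#' @export
summary.cox_fit <- function(object, bh = FALSE, ...) {
  se <- sqrt(diag(object$var))
  b <- object$coefficients
  p <- 2 * stats::pnorm(-abs(b / se))
  out <- data.frame(
    covariate = names(b), coef = b, hr = exp(b),
    hr_low = exp(b - 1.959964 * se), hr_high = exp(b + 1.959964 * se),
    p = p, row.names = NULL)
  if (bh) out$p_adj <- bh_adjust(p)
  class(out) <- c("cox_fit_summary", "data.frame")
  out
}

#' @export
plot.cox_fit <- function(x, ...) {
  bl <- x$baseline
  graphics::plot(stats::stepfun(bl$times, c(0, bl$cumhaz)),
                 do.points = FALSE, xlab = "time (months)",
                 ylab = expression(hat(Lambda)[0](t)),
                 main = "Breslow baseline cumulative hazard", ...)
  invisible(x)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Grambsch-Therneau style score test: for each covariate, the
#' correlation of its Schoenfeld residuals with a transform of the event
#' times, plus a global chi-square test across covariates. Small
#' p-values indicate departure from proportional hazards.
#'
#' @param fit a [fit_cox()] object with at least 2 events.
#' @param transform time transform: `"km"` (left-continuous Kaplan-Meier
#'   of the training data, the field's usual default), `"identity"` or
#'   `"rank"`.
#' @return a `schoenfeld_test` data.frame (one row per covariate plus a
#'   `GLOBAL` row) with `chisq`, `df`, `p`.
#' @export
schoenfeld_ph_test <- function(fit, transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events < 2L) stop_("need at least 2 events")
  beta <- fit$coefficients
  p <- length(beta)
  ord <- fit$sorted$ord
  ts <- fit$time[ord]; ss <- fit$status[ord]
  Xs <- sweep(fit$X[ord, , drop = FALSE], 2L, fit$center)
  grp <- fit$sorted$grp; gstart <- fit$sorted$gstart
  w <- exp(drop(Xs %*% beta))
  WX <- w * Xs
  rc0 <- revcumsum(w)
  rc1 <- revcumsum(WX)
  lower <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  ii <- lower[, 1L]; jj <- lower[, 2L]
  WXX <- w * (Xs[, ii, drop = FALSE] * Xs[, jj, drop = FALSE])
  rc2 <- revcumsum(WXX)

  death <- which(ss == 1)
  gj <- grp[death]
  st <- gstart[gj]
  S0 <- rc0[st]
  xbar <- rc1[st, , drop = FALSE] / S0
  sch <- Xs[death, , drop = FALSE] - xbar          # Schoenfeld residuals
  # per-event covariance of x over the risk set
  V2 <- rc2[st, , drop = FALSE] / S0 - xbar[, ii, drop = FALSE] * xbar[, jj, drop = FALSE]
  Vbar_pack <- colMeans(V2)
  Vbar <- matrix(0, p, p)
  Vbar[cbind(ii, jj)] <- Vbar_pack
  Vbar[cbind(jj, ii)] <- Vbar_pack

  tt <- ts[death]
  g <- switch(transform,
              identity = tt,
              rank = rank(tt),
              km = {
                km <- km_curve(data.frame(time = fit$time, event = fit$status))
                # left-continuous KM at the death times
                idx <- findInterval(tt - 1e-12, km$times)
                c(1, km$surv)[idx + 1L]
              })
  gc <- g - mean(g)
  u <- colSums(gc * sch)
  denom <- sum(gc^2)
  chisq_each <- u^2 / (denom * diag(Vbar))
  chisq_glob <- tryCatch(drop(t(u) %*% solve(denom * Vbar, u)),
                         error = function(e) NA_real_)
  out <- data.frame(
    covariate = c(names(beta), "GLOBAL"),
    chisq = c(chisq_each, chisq_glob),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(chisq_each, 1, lower.tail = FALSE),
          stats::pchisq(chisq_glob, p, lower.tail = FALSE)),
    row.names = NULL)
  class(out) <- c("schoenfeld_test", "data.frame")
  out
}
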