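#' Chart configuration
#'
#' Parameters of the two-sided risk-adjusted EWMA chart. `lambda` is the
#' EWMA weight (small values emphasize persistent small shifts; default
#' 0.1), `alpha` the target per-case false-alarm probability under
#' in-control conditions (default 0.005, i.e. one false alarm expected
#' per 200 monitored cases), `z0` the EWMA start value, and
#' `calibration_reps` the number of in-control Monte-Carlo sequences
#' used to calibrate the limit multiplier.
#'
#' @param lambda EWMA weight in (0, 1].
#' @param alpha per-case expected false-alarm rate in (0, 0.5).
#' @param z0 EWMA start value.
#' @param calibration_reps Monte-Carlo sequences for calibration
#'   (at least 100).
#' @param eps small positive floor on the expected cumulative hazard in
#'   the score denominator.
#' @param component `"mean"` (default): standardized martingale-residual
#'   score monitoring the mean survival risk; `"variance"`: the
#'   second-moment score monitoring excess risk variability (a
#'   random-effect-variance signal).
#' @param seed integer seed consumed by calibration.
#' @return object of class `chart_config`.
#' @export
chart_config <- function(lambda = 0.1, alpha = 0.005, z0 = 0,
                         calibration_reps = 500L, eps = 1e-8,
                         component = c("mean", "variance"), seed = NULL) {
  component <- match.arg(component)
  if (lambda <= 0 || lambda > 1) stop_("lambda must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 0.5) stop_("alpha must lie in (0, 0.5)")
  if (calibration_reps < 100L) stop_("calibration_reps must be at least 100")
  if (eps <= 0) stop_("eps must be positive")
  structure(list(lambda = lambda, alpha = alpha, z0 = z0,
                 calibration_reps = as.integer(calibration_reps),
                 eps = eps, component = component, seed = seed),
            class = "chart_config")
}

#' Per-case risk-adjusted scores
#'
#' For each monitored case, the expected event count under the Phase-I
#' model is `H_i = H0(t_i) * exp(beta' x_i)`. The default (mean
#' component) score is the standardized martingale residual
#' `U_i = (delta_i - H_i) / sqrt(max(H_i, eps))`: positive values mean
#' worse-than-expected survival, negative values better. The variance
#' component `V_i = (M_i^2 - H_i) / sqrt(max(2 H_i^2, eps))` tracks
#' excess variability of the risk (a nonzero random-effect variance).
#' Cases censored before the first Phase-I event time score 0 by
#' convention; follow-up beyond the baseline's support uses the last
#' baseline value (with a warning).
#'
#' @param records ordered test-arm patients (a [trial_cohort()] or
#'   data.frame with `time`, `event` and the fit's covariates).
#' @param phase1_fit the control-arm [fit_cox()].
#' @param config a [chart_config()].
#' @return numeric score vector, one per record, in input order.
#' @export
case_scores <- function(records, phase1_fit, config = chart_config()) {
  stopifnot(inherits(phase1_fit, "cox_fit"))
  if (!nrow(records)) return(numeric(0))
  X <- cox_design(records, names(phase1_fit$coefficients))
  w <- exp(drop(X %*% phase1_fit$coefficients))
  support_end <- max(phase1_fit$baseline$times)
  if (any(records$time > support_end))
    warning(sprintf(
      "%d record(s) exceed the baseline's support (%.3g); using its last value",
      sum(records$time > support_end), support_end), call. = FALSE)
  H <- w * cumhaz_at(phase1_fit$baseline, records$time)
  M <- records$event - H
  # The standardizing denominator is floored at the baseline's first
  # increment (scaled by the case's relative risk): below its first
  # event time the step baseline is exactly 0 and cannot resolve risks
  # smaller than that increment, and an unfloored denominator would let
  # a single early death dominate the whole chart. eps remains the
  # ultimate division guard.
  Hfloor <- pmax(H, w * phase1_fit$baseline$increments[1L], config$eps)
  U <- if (config$component == "mean") {
    M / sqrt(Hfloor)
  } else {
    (M^2 - H) / sqrt(pmax(2 * Hfloor^2, config$eps))
  }
  U[records$event == 0 & H == 0] <- 0
  U
}

#' EWMA smoothing
#'
#' `Z_t = lambda * U_t + (1 - lambda) * Z_{t-1}` with `Z_0 = z0`.
#'
#' @param U score vector (may be empty).
#' @param config a [chart_config()] supplying `lambda` and `z0`.
#' @return the EWMA series `Z`, same length as `U`.
#' @export
ewma_smooth <- function(U, config = chart_config()) {
  lambda <- config$lambda
  if (!length(U)) return(numeric(0))
  z <- numeric(length(U))
  prev <- config$z0
  for (t in seq_along(U)) {
    prev <- lambda * U[t] + (1 - lambda) * prev
    z[t] <- prev
  }
  z
}

# Exact EWMA variance-inflation factor at case index t (relative to the
# asymptote), so early cases get tighter limits.
ewma_varfactor <- function(t, lambda) {
  lambda / (2 - lambda) * (1 - (1 - lambda)^(2 * t))
}

#' Calibrate time-varying control limits by Monte Carlo
#'
#' Simulates `calibration_reps` in-control sequences of length
#' `n_sequence` from the Phase-I model (via [simulate_null_arm()]),
#' computes their EWMA series, and chooses per-side limit multipliers
#' `L_l`, `L_u` so that the pooled per-case crossing rate of
#' `c(t) - L_l * w(t)` and `c(t) + L_u * w(t)`, with half-width scale
#' `w(t) = sigma_U * sqrt(lambda/(2-lambda) * (1-(1-lambda)^(2t)))`, is
#' `alpha/2` on each side (total `alpha`). `sigma_U` and `mu_U` are the
#' pooled standard deviation and mean of the calibration scores; the
#' per-side calibration matters because the score distribution is
#' right-skewed.
#'
#' The centerline `c(t) = mu_U + (z0 - mu_U) (1-lambda)^t` is the exact
#' in-control mean path of the EWMA: the standardized score's
#' in-control expectation is not zero (the standardizing weight
#' `1/sqrt(H_i)` is correlated with the martingale residual; for fully
#' observed cases it is about `E[(1-E)/sqrt(E)] = sqrt(pi)/2` with
#' `E ~ Exp(1)`), so limits centered at `z0` itself would make the
#' two-sided chart asymmetric and insensitive on the low (improved
#' survival) side. Centering on the Monte-Carlo in-control mean path
#' restores symmetry at the configured false-alarm rate.
#'
#' @param phase1_fit the control-arm [fit_cox()].
#' @param covariate_source cohort supplying covariate rows for the
#'   in-control draws (typically the Phase-I control arm).
#' @param n_sequence length of each monitored sequence.
#' @param config a [chart_config()] with a seed.
#' @param censoring optional censoring law passed to
#'   [simulate_null_arm()].
#' @return object of class `chart_limits` with the multiplier `L`,
#'   `sigma_U`, and `lower(t)` / `upper(t)` limit functions.
#' @export
calibrate_limits <- function(phase1_fit, covariate_source, n_sequence,
                             config = chart_config(), censoring = NULL) {
  if (is.null(config$seed)) stop_("config$seed is required for calibration")
  if (n_sequence < 1L) stop_("n_sequence must be positive")
  R <- config$calibration_reps
  Z <- matrix(0, R, n_sequence)
  allU <- matrix(0, R, n_sequence)
  for (r in seq_len(R)) {
    arm <- simulate_null_arm(phase1_fit, covariate_source, n_sequence,
                             seed = substream_seed(config$seed, 31L, r),
                             censoring = censoring)
    U <- suppressWarnings(case_scores(arm, phase1_fit, config))
    allU[r, ] <- U
    Z[r, ] <- ewma_smooth(U, config)
  }
  sigma_U <- stats::sd(as.vector(allU))
  mu_U <- mean(allU)
  lam <- config$lambda
  center <- function(t) mu_U + (config$z0 - mu_U) * (1 - lam)^t
  sf <- sqrt(ewma_varfactor(seq_len(n_sequence), lam))
  # Per-side multipliers, each at alpha/2: the score is right-skewed
  # (early deaths score much higher than late survivors score low), so
  # one symmetric multiplier would spend the whole false-alarm budget on
  # the high side and leave the low side insensitive.
  dev <- sweep(Z, 2, center(seq_len(n_sequence))) /
    (sigma_U * matrix(sf, R, n_sequence, byrow = TRUE))
  L_u <- unname(stats::quantile(as.vector(dev), 1 - config$alpha / 2, type = 7))
  L_l <- unname(stats::quantile(as.vector(-dev), 1 - config$alpha / 2, type = 7))
  structure(list(
    L_l = L_l, L_u = L_u, sigma_U = sigma_U, mu_U = mu_U, lambda = lam,
    z0 = config$z0, alpha = config$alpha, n_sequence = n_sequence,
    calibration_reps = R, center = center,
    lower = function(t) center(t) - L_l * sigma_U * sqrt(ewma_varfactor(t, lam)),
    upper = function(t) center(t) + L_u * sigma_U * sqrt(ewma_varfactor(t, lam))
  ), class = "chart_limits")
}

#' @export
print.chart_limits <- function(x, ...) {
  cat(sprintf(
    "EWMA control limits: L_l = %.3f, L_u = %.3f, mu_U = %.3f, sigma_U = %.3f, lambda = %.2f, alpha = %.4f\n",
    x$L_l, x$L_u, x$mu_U, x$sigma_U, x$lambda, x$alpha))
  cat(sprintf("  calibrated on %d in-control sequences of length %d\n",
              x$calibration_reps, x$n_sequence))
  invisible(x)
}

#' Monitor a test arm against a Phase-I model
#'
#' Computes the case scores and EWMA series of an ordered test arm and
#' flags limit crossings: a low-side signal (`Z_t < L_l(t)`) indicates
#' significantly better survival than the Phase-I (control-arm) model
#' predicts; a high-side signal (`Z_t > L_u(t)`) significant
#' deterioration.
#'
#' @param test_arm ordered test-arm records.
#' @param phase1_fit the control-arm [fit_cox()].
#' @param limits a [calibrate_limits()] result for the same fit.
#' @param config the [chart_config()] used at calibration.
#' @return object of class `raes_chart`: a list with a `series`
#'   data.frame (`t`, `U`, `Z`, `lower`, `upper`, `signal_low`,
#'   `signal_high`) and the signalling case indices.
#' @export
monitor_sequence <- function(test_arm, phase1_fit, limits,
                             config = chart_config()) {
  stopifnot(inherits(limits, "chart_limits"))
  n <- nrow(test_arm)
  if (is.null(n) || n == 0L) {
    series <- data.frame(t = integer(0), U = numeric(0), Z = numeric(0),
                         lower = numeric(0), upper = numeric(0),
                         signal_low = logical(0), signal_high = logical(0))
    return(structure(list(series = series, signal_low = integer(0),
                          signal_high = integer(0), limits = limits,
                          config = config),
                     class = "raes_chart"))
  }
  U <- case_scores(test_arm, phase1_fit, config)
  Z <- ewma_smooth(U, config)
  tt <- seq_len(n)
  lo <- limits$lower(tt)
  hi <- limits$upper(tt)
  series <- data.frame(t = tt, U = U, Z = Z, lower = lo, upper = hi,
                       signal_low = Z < lo, signal_high = Z > hi)
  structure(list(series = series,
                 signal_low = which(series$signal_low),
                 signal_high = which(series$signal_high),
                 limits = limits, config = config),
            class = "raes_chart")
}

#' @export
print.raes_chart <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("Risk-adjusted EWMA chart: %d monitored case(s)\n", n))
  cat(sprintf("  low-side signals (improved survival): %s\n",
              if (length(x$signal_low)) paste(x$signal_low, collapse = ", ")
              else "none"))
  cat(sprintf("  high-side signals (worse survival):   %s\n",
              if (length(x$signal_high)) paste(x$signal_high, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
summary.raes_chart <- function(object, ...) {
  s <- object$series
  data.frame(n = nrow(s),
             n_signal_low = length(object$signal_low),
             n_signal_high = length(object$signal_high),
             signal_rate = if (nrow(s)) mean(s$signal_low | s$signal_high)
                           else NA_real_,
             final_Z = if (nrow(s)) s$Z[nrow(s)] else NA_real_)
}

#' @export
plot.raes_chart <- function(x, ...) {
  s <- x$series
  if (!nrow(s)) { graphics::plot.new(); return(invisible(x)) }
  ylim <- range(s$Z, s$lower, s$upper)
  graphics::plot(s$t, s$Z, type = "l", ylim = ylim, xlab = "case index",
                 ylab = expression(Z[t]),
                 main = "Risk-adjusted EWMA chart", ...)
  graphics::lines(s$t, s$lower, lty = 2, col = "grey40")
  graphics::lines(s$t, s$upper, lty = 2, col = "grey40")
  if (length(x$signal_low))
    graphics::points(x$signal_low, s$Z[x$signal_low], col = "blue", pch = 19)
  if (length(x$signal_high))
    graphics::points(x$signal_high, s$Z[x$signal_high], col = "red", pch = 19)
  invisible(x)
}

#' Operating characteristics of the calibrated chart
#'
#' Estimates low- and high-side per-case signal rates under a grid of
#' hazard shifts: each monitored sequence is drawn from the Phase-I
#' model with the stated log-hazard-ratio shift added to every linear
#' predictor, then monitored with the supplied limits.
#'
#' @param phase1_fit the control-arm [fit_cox()].
#' @param covariate_source cohort supplying covariate rows.
#' @param hazard_shifts numeric vector of log-hazard-ratio shifts
#'   (0 = in control; negative = improved survival).
#' @param config a [chart_config()] with a seed.
#' @param limits a [calibrate_limits()] result; calibrated on the fly
#'   when `NULL`.
#' @param n_sequence sequence length (default: the limits' length).
#' @param reps sequences per shift (default `config$calibration_reps`).
#' @return data.frame with one row per shift: low/high per-case signal
#'   rates and their binomial Monte-Carlo standard errors.
#' @export
oc_study <- function(phase1_fit, covariate_source, hazard_shifts,
                     config = chart_config(), limits = NULL,
                     n_sequence = NULL, reps = NULL) {
  if (!length(hazard_shifts)) stop_("hazard_shifts must be non-empty")
  if (any(!is.finite(hazard_shifts))) stop_("hazard shifts must be finite")
  if (is.null(config$seed)) stop_("config$seed is required")
  n_sequence <- n_sequence %||% (if (!is.null(limits)) limits$n_sequence
                                 else nrow(covariate_source))
  if (is.null(limits))
    limits <- calibrate_limits(phase1_fit, covariate_source, n_sequence,
                               config)
  reps <- reps %||% config$calibration_reps
  shifted_fit <- phase1_fit
  rows <- lapply(seq_along(hazard_shifts), function(k) {
    shift <- hazard_shifts[k]
    # apply the shift by scaling the baseline increments
    shifted_fit$baseline <- step_hazard(
      phase1_fit$baseline$times,
      phase1_fit$baseline$increments * exp(shift))
    low <- high <- 0L
    for (r in seq_len(reps)) {
      arm <- simulate_null_arm(shifted_fit, covariate_source, n_sequence,
                               seed = substream_seed(config$seed, 41L,
                                                     k * 100003L + r))
      ch <- monitor_sequence(arm, phase1_fit, limits, config)
      low <- low + length(ch$signal_low)
      high <- high + length(ch$signal_high)
    }
    ncases <- reps * n_sequence
    pl <- low / ncases; ph <- high / ncases
    data.frame(shift = shift, low_rate = pl, high_rate = ph,
               low_se = sqrt(pl * (1 - pl) / ncases),
               high_se = sqrt(ph * (1 - ph) / ncases),
               n_sequences = reps)
  })
  do.call(rbind, rows)
}
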