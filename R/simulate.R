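#' Synthetic trial configuration
#'
#' Full parameterization of a two-arm synthetic cohort with the
#' statistical structure the monitoring pipeline assumes: a control and
#' a treatment arm, baseline covariates (age, sex, ECOG performance
#' status, extent of disease, pain intensity), log-normal biomarker
#' concentrations, a Weibull proportional-hazards event-time model, an
#' optional treatment main effect and threshold treatment-by-biomarker
#' interactions, and right censoring (administrative horizon plus an
#' independent early-censoring fraction).
#'
#' Defaults emulate the monitored gemcitabine trial population: arm
#' sizes 246/234; ECOG = 1 with probability 0.81, distant metastasis
#' with probability 0.733, male with probability 0.533; pain intensity
#' as `100 * Beta(0.9, 2.4)` (right-skewed on `[0, 100]`, median approx.
#' 22); Weibull baseline with shape 1.2 and rate 0.0715, which puts the
#' control-arm median overall survival at approx. 5.9 months under the
#' default covariate mix; prognostic log-hazard ratios
#' `log(0.521)` (ECOG), `log(2.054)` (extent of disease), `log(1.004)`
#' (per pain-intensity point); treatment main log-HR `-0.065` (median
#' 6.24 vs 5.91 months). Fifteen biomarkers with plausible log-normal
#' scales are included by default.
#'
#' @param n_control,n_treatment arm sizes.
#' @param age list with `mean` and `sd` (years).
#' @param sex_p,ecog_p,eod_p Bernoulli probabilities of male sex,
#'   ECOG = 1 and distant metastasis.
#' @param pi_beta length-2 vector of Beta shapes for pain intensity
#'   (scaled to `[0, 100]`).
#' @param markers named list; each element `c(meanlog, sdlog)` of a
#'   log-normal concentration model.
#' @param weibull named vector `c(shape, rate)` of the baseline hazard
#'   `h0(t) = rate * shape * t^(shape-1)`.
#' @param beta named prognostic log-hazard ratios for `ecog`, `eod`,
#'   `pi`.
#' @param treatment_loghr treatment main-effect log-hazard ratio.
#' @param interactions list of threshold interaction effects, each a
#'   list with `marker`, `quantile` (true cut-point as a quantile of the
#'   marker's generating distribution, in (0,1)), `loghr` (log-HR added
#'   to treatment-arm patients on the `side` of the cut), and `side`
#'   (`"high"`: marker above the cut, the default; or `"low"`).
#' @param censoring list with `horizon` (administrative censoring time,
#'   months) and `frac` (probability of independent uniform early
#'   censoring on `(0, horizon)`).
#' @param seed integer seed; mandatory for any stochastic call.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_control = 246L, n_treatment = 234L,
                       age = list(mean = 64, sd = 11),
                       sex_p = 0.533, ecog_p = 0.81, eod_p = 0.733,
                       pi_beta = c(0.9, 2.4),
                       markers = default_marker_models(),
                       weibull = c(shape = 1.2, rate = 0.0715),
                       beta = c(ecog = log(0.521), eod = log(2.054),
                                pi = log(1.004)),
                       treatment_loghr = -0.065,
                       interactions = list(),
                       censoring = list(horizon = 36, frac = 0.10),
                       seed = NULL) {
  stopifnot(n_control >= 0, n_treatment >= 0,
            weibull[["shape"]] > 0, weibull[["rate"]] > 0,
            sex_p >= 0, sex_p <= 1, ecog_p >= 0, ecog_p <= 1,
            eod_p >= 0, eod_p <= 1,
            censoring$frac >= 0, censoring$frac <= 1, censoring$horizon > 0)
  for (ia in interactions) {
    if (!ia$marker %in% names(markers))
      stop_("interaction marker '%s' absent from the biomarker model", ia$marker)
    if (ia$quantile <= 0 || ia$quantile >= 1)
      stop_("interaction cut-point quantile must lie in (0, 1)")
  }
  structure(list(n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment),
                 age = age, sex_p = sex_p, ecog_p = ecog_p, eod_p = eod_p,
                 pi_beta = pi_beta, markers = markers, weibull = weibull,
                 beta = beta, treatment_loghr = treatment_loghr,
                 interactions = interactions, censoring = censoring,
                 seed = seed),
            class = "sim_config")
}

# Plausible log-normal scales for the fifteen plasma biomarkers of the
# monitored trial; marginal distributions are unpublished, so these are
# an assumption (log-normal, sdlog 1) at magnitudes matching the
# reported cut-point scales.
default_marker_models <- function() {
  scales <- c(CXCL6 = 3e5, CEA = 5e3, `CA19-9` = 1e4, `HIF1-alpha` = 2e3,
              IL6 = 50, IL8 = 80, REG4 = 1e4, CXCL9 = 500, IGF2 = 2e5,
              MMP1 = 4e3, PF4 = 1e6, HER2 = 6e3, AXL = 3e4, BMP2 = 1e5,
              GAS6 = 2e4)
  lapply(as.list(scales), function(s) c(meanlog = log(s), sdlog = 1))
}

#' Read / write a simulation configuration as YAML
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$markers <- lapply(y$markers, function(m)
    c(meanlog = m$meanlog, sdlog = m$sdlog))
  y$weibull <- c(shape = y$weibull$shape, rate = y$weibull$rate)
  y$beta <- unlist(y$beta)
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  y <- unclass(config)
  y$markers <- lapply(y$markers, as.list)
  y$weibull <- as.list(y$weibull)
  y$beta <- as.list(y$beta)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Inverse-transform Weibull proportional-hazards survival times
#'
#' `T = (-log(u) / (rate * exp(eta)))^(1/shape)` for `u ~ Uniform(0,1)`;
#' the induced hazard is `rate * shape * t^(shape-1) * exp(eta)`, i.e.
#' proportional hazards in the linear predictor by construction.
#'
#' @param eta linear predictor (log relative hazard), vectorized.
#' @param shape,rate Weibull shape `k > 0` and rate `> 0`.
#' @param u uniform(0,1) draws, recycled against `eta`.
#' @return positive survival times.
#' @export
draw_survival_time <- function(eta, shape, rate, u) {
  stopifnot(shape > 0, rate > 0)
  if (any(u <= 0 | u >= 1)) stop_("u must lie strictly in (0, 1)")
  (-log(u) / (rate * exp(eta)))^(1 / shape)
}

#' Simulate a two-arm trial cohort
#'
#' Draws covariates, biomarkers and Weibull proportional-hazards event
#' times per [sim_config()]; threshold interaction effects apply only to
#' treatment-arm patients on the configured side of each true cut-point;
#' censoring is `min(T, C)` with `event = 1{T <= C}`. Reproducible given
#' the config seed: one global seed expands into independent substreams
#' for covariates, biomarkers, event times and censoring.
#'
#' @param config a [sim_config()] with a non-`NULL` seed.
#' @return a [trial_cohort()]; attribute `"truth"` records the true
#'   cut-point value of every configured interaction.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop_("config$seed is mandatory")
  n <- config$n_control + config$n_treatment
  arm <- rep(c("control", "treatment"),
             c(config$n_control, config$n_treatment))

  set.seed(substream_seed(config$seed, 1L))    # covariates
  age <- stats::rnorm(n, config$age$mean, config$age$sd)
  sex <- stats::rbinom(n, 1L, config$sex_p)
  ecog <- stats::rbinom(n, 1L, config$ecog_p)
  eod <- stats::rbinom(n, 1L, config$eod_p)
  pival <- 100 * stats::rbeta(n, config$pi_beta[1L], config$pi_beta[2L])

  set.seed(substream_seed(config$seed, 2L))    # biomarkers
  mk <- lapply(config$markers, function(m)
    stats::rlnorm(n, m[["meanlog"]], m[["sdlog"]]))

  eta <- config$beta[["ecog"]] * ecog + config$beta[["eod"]] * eod +
    config$beta[["pi"]] * pival +
    config$treatment_loghr * (arm == "treatment")
  truth <- list()
  for (ia in config$interactions) {
    m <- config$markers[[ia$marker]]
    cut <- stats::qlnorm(ia$quantile, m[["meanlog"]], m[["sdlog"]])
    side <- ia$side %||% "high"
    hit <- if (side == "high") mk[[ia$marker]] > cut else mk[[ia$marker]] <= cut
    eta <- eta + ia$loghr * hit * (arm == "treatment")
    truth[[ia$marker]] <- cut
  }

  set.seed(substream_seed(config$seed, 3L))    # event times
  u <- stats::runif(n)
  T <- draw_survival_time(eta, config$weibull[["shape"]],
                          config$weibull[["rate"]], u)

  set.seed(substream_seed(config$seed, 4L))    # censoring
  C <- rep(config$censoring$horizon, n)
  early <- stats::runif(n) < config$censoring$frac
  C[early] <- stats::runif(sum(early), 0, config$censoring$horizon)
  time <- pmin(T, C)
  event <- as.integer(T <= C)
  time <- pmax(time, 1e-6)                      # guard against zero times

  df <- data.frame(id = sprintf("P%04d", seq_len(n)), arm = arm,
                   time = time, event = event, age = age, sex = sex,
                   ecog = ecog, eod = eod, pi = pival,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(mk)) df[[nm]] <- mk[[nm]]
  out <- trial_cohort(df)
  attr(out, "truth") <- truth
  out
}

#' Simulate an in-control arm from a fitted Phase-I model
#'
#' Resamples covariate rows with replacement from `covariate_source` and
#' draws event times from the fitted Cox model itself: a unit
#' exponential target is inverted through the Breslow baseline
#' (piecewise-constant inversion) scaled by the fitted linear predictor.
#' Targets beyond the baseline's support are censored at its last event
#' time. This is the in-control generator used to calibrate and validate
#' the chart's control limits.
#'
#' @param phase1_fit a [fit_cox()] with a non-empty baseline.
#' @param covariate_source a [trial_cohort()] (typically the Phase-I
#'   control arm) supplying covariate rows.
#' @param n number of cases (0 gives an empty cohort).
#' @param seed integer seed.
#' @param censoring optional list `(horizon, frac)` applied as in
#'   [simulate_cohort()]; `NULL` (default) for none.
#' @return a [trial_cohort()] with `arm = "treatment"`, in resampled
#'   order (the monitoring order).
#' @export
simulate_null_arm <- function(phase1_fit, covariate_source, n, seed,
                              censoring = NULL) {
  stopifnot(inherits(phase1_fit, "cox_fit"))
  if (length(phase1_fit$baseline$times) == 0L)
    stop_("phase1_fit has an empty baseline hazard")
  if (n < 0) stop_("n must be nonnegative")
  src <- as.data.frame(covariate_source)
  if (n == 0L) {
    out <- src[0L, , drop = FALSE]
    class(out) <- c("trial_cohort", "data.frame")
    return(out)
  }
  set.seed(substream_seed(seed, 11L))
  idx <- sample.int(nrow(src), n, replace = TRUE)
  df <- src[idx, , drop = FALSE]
  rownames(df) <- NULL
  df$id <- sprintf("N%05d", seq_len(n))
  df$arm <- "treatment"

  X <- cox_design(df, names(phase1_fit$coefficients))
  lp <- drop(X %*% phase1_fit$coefficients)
  set.seed(substream_seed(seed, 12L))
  u <- stats::runif(n)
  target <- -log(u) / exp(lp)
  T <- cumhaz_invert(phase1_fit$baseline, target)
  support_end <- max(phase1_fit$baseline$times)
  event <- as.integer(!is.na(T))
  T[is.na(T)] <- support_end

  if (!is.null(censoring)) {
    set.seed(substream_seed(seed, 13L))
    C <- rep(censoring$horizon, n)
    early <- stats::runif(n) < censoring$frac
    C[early] <- stats::runif(sum(early), 0, censoring$horizon)
    event <- as.integer(event == 1L & T <= C)
    T <- pmin(T, C)
  }
  df$time <- pmax(T, 1e-6)
  df$event <- event
  if (all(cohort_required_cols() %in% names(df))) {
    trial_cohort(df)
  } else {
    # covariate source carried only the model covariates; skip the full
    # record validation but keep the class for downstream dispatch
    class(df) <- unique(c("trial_cohort", class(df)))
    df
  }
}

#' Simulate new arms from a fitted Cox model
#'
#' `simulate()` method wrapping [simulate_null_arm()]: draws `nsim`
#' in-control arms from the fitted model.
#'
#' @param object a [fit_cox()] object.
#' @param nsim number of simulated arms.
#' @param seed integer seed.
#' @param covariate_source cohort supplying covariate rows (default: the
#'   fit's own training data).
#' @param n cases per arm (default: the training-set size).
#' @param ... passed to [simulate_null_arm()].
#' @return list of [trial_cohort()]s (a single cohort if `nsim = 1`).
#' @export
simulate.cox_fit <- function(object, nsim = 1, seed = NULL,
                             covariate_source = NULL, n = NULL, ...) {
  if (is.null(seed)) stop_("seed is required")
  if (is.null(covariate_source)) {
    covariate_source <- as.data.frame(object$X)
    covariate_source$time <- object$time
    covariate_source$event <- object$status
  }
  n <- n %||% object$n
  out <- lapply(seq_len(nsim), function(r)
    simulate_null_arm(object, covariate_source, n,
                      seed = substream_seed(seed, 20L, r), ...))
  if (nsim == 1) out[[1L]] else out
}
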