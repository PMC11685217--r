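#' Maximally selected log-rank cut-point for a biomarker
#'
#' Scans every observed marker value whose induced split ("high" means
#' strictly greater than the candidate) leaves at least `minprop` of
#' the patients and at least one event on each side, computes the
#' standardized log-rank statistic of the induced two-group comparison,
#' and returns the candidate maximizing its absolute value (ties broken
#' toward the smaller cut-point).
#'
#' No selection-adjusted p-value is attached: the maximally selected
#' statistic's null distribution is not chi-square, and downstream
#' inference here relies on the interaction model and bootstrap
#' stability instead.
#'
#' @param cohort a [trial_cohort()].
#' @param marker marker column name.
#' @param minprop minimum proportion of patients on each side of a
#'   candidate split (default 0.1).
#' @return object of class `cutpoint_result`: `marker`, `cutpoint`,
#'   `statistic` (signed z at the selected cut), `abs_statistic`,
#'   `profile` (data.frame of candidate cuts and signed z), `minprop`.
#' @export
max_logrank_cutpoint <- function(cohort, marker, minprop = 0.1) {
  if (!marker %in% names(cohort)) stop_("unknown marker '%s'", marker)
  if (minprop <= 0 || minprop >= 0.5) stop_("minprop must lie in (0, 0.5)")
  x <- cohort[[marker]]
  n <- length(x)
  if (length(unique(x)) < 2L) stop_("marker '%s' is constant", marker)
  xs <- sort(unique(x))
  cand <- xs[-length(xs)]                     # splitting at max leaves no high group
  nlow <- findInterval(cand, sort(x))         # count of x <= cand
  keep <- nlow / n >= minprop & (n - nlow) / n >= minprop
  cand <- cand[keep]
  if (!length(cand)) stop_("no candidate split satisfies minprop = %g", minprop)
  G <- outer(x, cand, ">")
  # at least one event on each side
  ev <- cohort$event == 1
  ehigh <- colSums(G & ev)
  elow <- sum(ev) - ehigh
  cand_ok <- ehigh >= 1 & elow >= 1
  cand <- cand[cand_ok]
  if (!length(cand)) stop_("no candidate split leaves an event on both sides")
  G <- G[, cand_ok, drop = FALSE]
  st <- logrank_stats(cohort$time, cohort$event, G)
  best <- which.max(abs(st$z))                # first max = smaller cut on ties
  structure(list(marker = marker, cutpoint = cand[best],
                 statistic = st$z[best], abs_statistic = abs(st$z[best]),
                 profile = data.frame(cut = cand, z = st$z),
                 minprop = minprop),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "Maximally selected log-rank cut-point for %s: %.6g (|z| = %.3f over %d candidates)\n",
    x$marker, x$cutpoint, x$abs_statistic, nrow(x$profile)))
  invisible(x)
}

#' @export
plot.cutpoint_result <- function(x, ...) {
  graphics::plot(x$profile$cut, abs(x$profile$z), type = "l",
                 xlab = x$marker, ylab = "|standardized log-rank|",
                 main = sprintf("Cut-point profile: %s", x$marker), ...)
  graphics::abline(v = x$cutpoint, lty = 2, col = "red")
  invisible(x)
}

# Dichotomize: "high" = strictly greater than the cut-point.
marker_high <- function(cohort, marker, cutpoint) {
  as.numeric(cohort[[marker]] > cutpoint)
}

# Interaction-term Wald p-value only (no subgroup summaries); the lean
# path used inside the bootstrap loop.
interaction_pvalue <- function(cohort, marker, cutpoint,
                               adjust = c("ecog", "eod", "pi"),
                               ties = "efron") {
  high <- marker_high(cohort, marker, cutpoint)
  treat <- as.numeric(cohort$arm == "treatment")
  if (any(table(factor(treat, levels = 0:1), factor(high, levels = 0:1)) == 0))
    stop_("empty cell in the arm x marker-class layout")
  df <- as.data.frame(cohort)
  df$.high <- high
  df$.inter <- treat * high
  fit <- fit_cox(df, c("treatment", ".high", ".inter", adjust), ties = ties)
  b <- coef(fit)[".inter"]
  unname(2 * stats::pnorm(-abs(b / sqrt(vcov(fit)[".inter", ".inter"]))))
}

#' Treatment-by-biomarker interaction Cox model
#'
#' Dichotomizes the marker at `cutpoint` (high = strictly greater) and
#' fits a Cox model with treatment, the binary marker class, their
#' product, and the adjustment covariates. Also reports, per marker
#' class, the within-subgroup treatment hazard ratio (treatment plus
#' the same adjustment covariates) and Kaplan-Meier median survival per
#' arm. A significant interaction term marks the marker as predictive
#' (treatment-effect-modifying) rather than merely prognostic.
#'
#' @param cohort a [trial_cohort()] with both arms.
#' @param marker marker column name.
#' @param cutpoint dichotomization threshold.
#' @param adjust adjustment covariates (default ECOG, extent of disease
#'   and pain intensity; use `character(0)` for the unadjusted model).
#' @param ties passed to [fit_cox()].
#' @return object of class `interaction_result`.
#' @export
interaction_cox <- function(cohort, marker, cutpoint,
                            adjust = c("ecog", "eod", "pi"),
                            ties = "efron") {
  high <- marker_high(cohort, marker, cutpoint)
  treat <- as.numeric(cohort$arm == "treatment")
  cells <- table(factor(treat, levels = 0:1), factor(high, levels = 0:1))
  if (any(cells == 0))
    stop_("empty cell in the arm x marker-class layout for %s at %.6g",
          marker, cutpoint)
  df <- as.data.frame(cohort)
  df$.high <- high
  df$.inter <- treat * high
  covs <- c("treatment", ".high", ".inter", adjust)
  fit <- fit_cox(df, covs, ties = ties)
  b <- coef(fit)[".inter"]
  se <- sqrt(vcov(fit)[".inter", ".inter"])
  p <- 2 * stats::pnorm(-abs(b / se))

  subgroup <- lapply(c(low = 0, high = 1), function(h) {
    sub <- df[df$.high == h, , drop = FALSE]
    sfit <- fit_cox(sub, c("treatment", adjust), ties = ties)
    tb <- coef(sfit)["treatment"]
    tse <- sqrt(vcov(sfit)["treatment", "treatment"])
    list(
      n = nrow(sub),
      hr = unname(exp(tb)),
      hr_low = unname(exp(tb - 1.959964 * tse)),
      hr_high = unname(exp(tb + 1.959964 * tse)),
      p = unname(2 * stats::pnorm(-abs(tb / tse))),
      median_control = km_curve(sub[sub$arm == "control", ])$median,
      median_treatment = km_curve(sub[sub$arm == "treatment", ])$median)
  })

  structure(list(marker = marker, cutpoint = cutpoint,
                 interaction_loghr = unname(b),
                 interaction_hr = unname(exp(b)),
                 ci = unname(exp(b + c(-1, 1) * 1.959964 * se)),
                 se = unname(se), p = unname(p),
                 subgroup = subgroup, adjust = adjust, fit = fit,
                 bootstrap = NULL),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, digits = 3, ...) {
  cat(sprintf("Treatment x %s interaction at cut-point %.6g\n",
              x$marker, x$cutpoint))
  cat(sprintf("  interaction HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$interaction_hr, x$ci[1], x$ci[2], x$p))
  for (nm in names(x$subgroup)) {
    s <- x$subgroup[[nm]]
    cat(sprintf(
      "  %s class (n=%d): treatment HR %.3f (%.3f-%.3f), p = %.4g; median OS %s vs %s months\n",
      nm, s$n, s$hr, s$hr_low, s$hr_high, s$p,
      formatC(s$median_treatment, digits = digits, format = "g"),
      formatC(s$median_control, digits = digits, format = "g")))
  }
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap stability: %.1f%% significant of %d used replicate(s)\n",
                100 * x$bootstrap$proportion, x$bootstrap$n_used))
  invisible(x)
}

#' Bootstrap stability of a dichotomized interaction
#'
#' Resamples patients with replacement `B` times; in each replicate the
#' marker is dichotomized at the FIXED cut-point, the interaction model
#' is refit, and significance of the interaction term (p < 0.05) is
#' recorded. The returned proportion of significant replicates measures
#' the stability of the cut-point-based interaction finding.
#' Replicates with an empty arm-by-class cell (or a failed fit) are
#' skipped and tallied. Optionally the cut-point is re-estimated per
#' replicate (`refit_cutpoint = TRUE`), a stricter assessment.
#'
#' @param cohort a [trial_cohort()].
#' @param marker marker column name.
#' @param cutpoint fixed dichotomization threshold.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param adjust adjustment covariates for the interaction model.
#' @param refit_cutpoint re-estimate the cut-point in each replicate.
#' @param level significance level (default 0.05).
#' @return object of class `bootstrap_stability`: `proportion`,
#'   `n_significant`, `n_used`, `n_skipped`, `B`.
#' @export
bootstrap_cutpoint_stability <- function(cohort, marker, cutpoint, B,
                                         seed, adjust = c("ecog", "eod", "pi"),
                                         refit_cutpoint = FALSE,
                                         level = 0.05) {
  if (B < 1) stop_("B must be at least 1")
  n <- nrow(cohort)
  set.seed(substream_seed(seed, 51L))
  sig <- 0L; used <- 0L; skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- as.data.frame(cohort)[idx, , drop = FALSE]
    boot$id <- seq_len(n)                 # ids must be unique in a resample
    rownames(boot) <- NULL
    class(boot) <- c("trial_cohort", "data.frame")
    res <- tryCatch({
      cp <- if (refit_cutpoint)
        max_logrank_cutpoint(boot, marker)$cutpoint else cutpoint
      interaction_pvalue(boot, marker, cp, adjust = adjust)
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1L
    else { used <- used + 1L; if (res < level) sig <- sig + 1L }
  }
  structure(list(proportion = if (used) sig / used else NA_real_,
                 n_significant = sig, n_used = used, n_skipped = skipped,
                 B = as.integer(B)),
            class = "bootstrap_stability")
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat(sprintf(
    "Bootstrap stability: %.1f%% significant (%d of %d used; %d skipped of %d)\n",
    100 * x$proportion, x$n_significant, x$n_used, x$n_skipped, x$B))
  invisible(x)
}

#' Subgroup-level chart monitoring
#'
#' Splits the cohort at the marker cut-point and runs the full two-phase
#' chart within each marker class: Phase I refits the Cox model on that
#' class's control-arm patients, control limits are recalibrated for the
#' class's treatment-arm size, and the class's treatment-arm patients
#' are monitored. Low-side signals inside one class but not the other
#' indicate a treatment-sensitive subpopulation.
#'
#' @param cohort a [trial_cohort()] with both arms.
#' @param marker marker column name.
#' @param cutpoint dichotomization threshold.
#' @param config a [chart_config()] with a seed.
#' @param covariates Phase-I covariates (default ECOG, extent of
#'   disease, pain intensity).
#' @param min_events minimum control-arm events required per subgroup
#'   (default 10).
#' @return named list of two [monitor_sequence()] charts (`high`,
#'   `low`).
#' @export
subgroup_charts <- function(cohort, marker, cutpoint,
                            config = chart_config(),
                            covariates = c("ecog", "eod", "pi"),
                            min_events = 10L) {
  high <- marker_high(cohort, marker, cutpoint)
  out <- list()
  for (nm in c("high", "low")) {
    sub <- cohort[if (nm == "high") high == 1 else high == 0, , drop = FALSE]
    ctrl <- sub[sub$arm == "control", , drop = FALSE]
    test <- sub[sub$arm == "treatment", , drop = FALSE]
    if (sum(ctrl$event) < min_events)
      stop_("subgroup '%s' has only %d control-arm event(s); need %d",
            nm, sum(ctrl$event), min_events)
    fit <- fit_cox(ctrl, covariates)
    cfg <- config
    cfg$seed <- substream_seed(config$seed %||% 0L, 61L,
                               if (nm == "high") 1L else 2L)
    lim <- calibrate_limits(fit, ctrl, max(nrow(test), 1L), cfg)
    out[[nm]] <- monitor_sequence(test, fit, lim, cfg)
  }
  out
}
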