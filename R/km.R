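#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with at-risk counts and the median survival
#' time, defined as the smallest time at which the estimated survival
#' drops to 0.5 or below (`NA` if the curve never reaches 0.5).
#'
#' @param records data.frame with `time` and `event` columns (e.g. a
#'   [trial_cohort()] or a subset of one).
#' @return object of class `km_curve` with `times`, `surv`, `n_risk`,
#'   `n_event`, `median`, `n`.
#' @export
km_curve <- function(records) {
  if (!nrow(records)) stop_("records must be non-empty")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(records))
  med <- if (any(sf$surv <= 0.5)) sf$time[which(sf$surv <= 0.5)[1L]] else NA_real_
  structure(list(times = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, median = med, n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$times, c(1, x$surv)), do.points = FALSE,
                 ylim = c(0, 1), xlab = "time (months)", ylab = "S(t)",
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

# Standardized log-rank statistics for one or many binary groupings at
# once. G is an n x C logical/0-1 matrix; column c defines "group 1".
# Returns observed-minus-expected, hypergeometric variance and the
# signed z = (O-E)/sqrt(V) per column. Positive z means group 1 dies
# faster (worse survival).
logrank_stats <- function(time, event, G) {
  G <- as.matrix(G) * 1
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; ss <- event[ord]
  Gs <- G[ord, , drop = FALSE]
  newgrp <- !duplicated(ts)
  grp <- cumsum(newgrp)
  gstart <- which(newgrp)
  d <- rowsum(ss, grp)[, 1L]
  egi <- which(d > 0)
  if (!length(egi)) stop_("no events")
  R <- revcumsum(Gs)                       # at-risk count in group 1
  n1 <- R[gstart[egi], , drop = FALSE]
  d1 <- rowsum(ss * Gs, grp)[egi, , drop = FALSE]
  nj <- (n - gstart + 1L)[egi]
  dj <- d[egi]
  frac <- n1 / nj
  omE <- colSums(d1 - dj * frac)
  vterm <- dj * frac * (1 - frac) * ifelse(nj > 1, (nj - dj) / (nj - 1), 0)
  V <- colSums(vterm)
  z <- ifelse(V > 0, omE / sqrt(V), NA_real_)
  list(omE = omE, V = V, z = z)
}

#' Two-sample log-rank test
#'
#' Returns the 1-df chi-square statistic, its p-value, and the signed
#' standardized form `z = (O1 - E1)/sqrt(V)` (positive when `group1`
#' experiences more deaths than expected, i.e. worse survival).
#'
#' @param group1,group2 data.frames with `time` and `event` columns.
#' @return list with `chisq`, `p`, `z`.
#' @export
logrank_test <- function(group1, group2) {
  if (!nrow(group1) || !nrow(group2)) stop_("both groups must be non-empty")
  time <- c(group1$time, group2$time)
  event <- c(group1$event, group2$event)
  g <- c(rep(1L, nrow(group1)), rep(0L, nrow(group2)))
  st <- logrank_stats(time, event, matrix(g, ncol = 1L))
  chisq <- st$z^2
  list(chisq = unname(chisq),
       p = unname(stats::pchisq(chisq, 1, lower.tail = FALSE)),
       z = unname(st$z))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, returned in the
#' input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
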