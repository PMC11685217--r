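# Fixture builders used across the suite. Everything is generated in
# code under explicit seeds; nothing is read from disk.

# Minimal valid cohort data.frame with one biomarker column.
make_cohort_df <- function(n = 60, seed = 1, marker = "mk") {
  set.seed(seed)
  d <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    arm = sample(c("control", "treatment"), n, replace = TRUE),
    time = round(stats::rexp(n, 0.2) + 0.05, 3),
    event = stats::rbinom(n, 1, 0.8),
    age = round(stats::rnorm(n, 62, 10), 1),
    sex = stats::rbinom(n, 1, 0.5),
    ecog = stats::rbinom(n, 1, 0.8),
    eod = stats::rbinom(n, 1, 0.7),
    pi = round(stats::runif(n, 0, 100), 2),
    stringsAsFactors = FALSE)
  d[[marker]] <- round(stats::rlnorm(n, 8, 1), 2)
  d
}

make_cohort <- function(n = 60, seed = 1, marker = "mk") {
  trial_cohort(make_cohort_df(n, seed, marker))
}

# Survival-only frame for Cox / KM fixtures.
make_surv_df <- function(n, seed, p = 2, beta = NULL, cens_rate = 0.05) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- beta %||% rep(0, p)
  eta <- drop(X %*% beta)
  T <- stats::rexp(n, rate = exp(eta))
  C <- stats::rexp(n, rate = cens_rate)
  d <- data.frame(time = pmin(T, C), event = as.integer(T <= C))
  cbind(d, as.data.frame(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force maximally selected cut-point via survival::survdiff,
# mirroring the candidate filter and smaller-cut tie rule.
brute_force_cutpoint <- function(cohort, marker, minprop = 0.1) {
  x <- cohort[[marker]]
  n <- length(x)
  xs <- sort(unique(x))
  cand <- xs[-length(xs)]
  nlow <- findInterval(cand, sort(x))
  cand <- cand[nlow / n >= minprop & (n - nlow) / n >= minprop]
  best <- NULL; bz <- -Inf
  for (c0 in cand) {
    hi <- x > c0
    if (sum(cohort$event[hi]) < 1 || sum(cohort$event[!hi]) < 1) next
    sd0 <- survival::survdiff(survival::Surv(time, event) ~ hi,
                              data = as.data.frame(cohort))
    z <- sqrt(sd0$chisq)
    if (z > bz + 1e-10) { bz <- z; best <- c0 }
  }
  list(cutpoint = best, abs_statistic = bz)
}
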