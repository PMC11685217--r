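#' Trial cohort objects
#'
#' A `trial_cohort` is a validated `data.frame` of patient records with
#' the canonical columns `id`, `arm` (`"control"` or `"treatment"`),
#' `time` (positive follow-up in months), `event` (1 = death observed,
#' 0 = censored), `age` (years), `sex` (0 female / 1 male), `ecog`
#' (0 fully active / 1 limited activity), `eod` (0 locally advanced /
#' 1 distant metastatic), `pi` (pain intensity on a 0--100 scale), and
#' one additional numeric column per biomarker (positive concentrations).
#' Row order is preserved everywhere: it is the Phase-II monitoring order.
#'
#' @param df data.frame holding the columns above.
#' @return `df` with class `trial_cohort` prepended, after validation.
#' @seealso [read_cohort()], [simulate_cohort()], [marker_names()]
#' @export
trial_cohort <- function(df) {
  req <- cohort_required_cols()
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop_("missing required column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id))
    stop_("patient ids must be unique")
  if (!all(df$arm %in% c("control", "treatment")))
    stop_("arm must be 'control' or 'treatment'")
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad))
    stop_("event must be 0 or 1; offending row id(s): %s",
          paste(df$id[bad], collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop_("follow-up time must be finite and > 0")
  if (any(df$pi < 0 | df$pi > 100))
    stop_("pi (pain intensity) must lie in [0, 100]")
  mk <- setdiff(names(df), req)
  for (m in mk) {
    v <- df[[m]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop_("biomarker '%s' must be finite and > 0", m)
  }
  df$arm <- as.character(df$arm)
  class(df) <- unique(c("trial_cohort", class(df)))
  df
}

cohort_required_cols <- function() {
  c("id", "arm", "time", "event", "age", "sex", "ecog", "eod", "pi")
}

#' Biomarker column names of a cohort
#' @param cohort a [trial_cohort()].
#' @return character vector of marker names (possibly empty).
#' @export
marker_names <- function(cohort) {
  setdiff(names(cohort), cohort_required_cols())
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat(sprintf(
    "Trial cohort: %d patients (%d control, %d treatment), %d events, %d biomarker(s)\n",
    nrow(x), sum(x$arm == "control"), sum(x$arm == "treatment"),
    sum(x$event), length(marker_names(x))))
  if (length(marker_names(x)))
    cat("  markers:", paste(marker_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' The documented CSV schema is: `id, arm, time_months, event, age, sex,
#' ecog, eod, pi`, followed by one numeric column per biomarker (UTF-8,
#' `.` decimal separator). Records with any missing biomarker value are
#' dropped, mirroring the complete-case policy of the analysis; the
#' number dropped is reported via [message()]. Row order of the retained
#' records is preserved.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (`id`, `arm`, `time_months`, ...) to the names actually used in
#'   the file, e.g. `c(time_months = "os_months")`.
#' @param drop_missing_markers drop records with missing biomarkers
#'   (default `TRUE`, the complete-case policy); if `FALSE` missing values
#'   are kept as `NA` and downstream marker analyses must handle them.
#' @return a [trial_cohort()].
#' @export
read_cohort <- function(path, schema = NULL, drop_missing_markers = TRUE) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("id", "arm", "time_months", "event", "age", "sex",
                 "ecog", "eod", "pi")
  file_names <- canonical
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), canonical)
    if (length(unknown))
      stop_("schema maps unknown column(s): %s", paste(unknown, collapse = ", "))
    file_names[match(names(schema), canonical)] <- unname(schema)
  }
  missing <- file_names[!file_names %in% names(df)]
  if (length(missing))
    stop_("missing required column(s): %s", paste(missing, collapse = ", "))
  names(df)[match(file_names, names(df))] <- canonical
  names(df)[names(df) == "time_months"] <- "time"

  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad))
    stop_("event must be 0 or 1; offending row id(s): %s",
          paste(df$id[bad], collapse = ", "))

  mk <- setdiff(names(df), cohort_required_cols())
  if (length(mk) && drop_missing_markers) {
    mkm <- as.matrix(df[mk])
    mode(mkm) <- "numeric"
    incomplete <- rowSums(is.na(mkm)) > 0L
    if (any(incomplete)) {
      message(sprintf("read_cohort: dropped %d record(s) with missing biomarker values",
                      sum(incomplete)))
      df <- df[!incomplete, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  trial_cohort(df)
}

#' Write a cohort in the documented CSV schema
#' @param cohort a [trial_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  names(df)[names(df) == "time"] <- "time_months"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for association in a 2x2 contingency table.
#' The two-sided rule sums the hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one,
#' the convention of mainstream statistical software.
#'
#' @param table 2x2 matrix of nonnegative integer counts; all margins
#'   must be positive.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(141, 115, 105, 119), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_("table must be 2x2")
  if (any(!is.finite(table)) || any(table < 0) || any(table != round(table)))
    stop_("table must hold nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_("all margins must be positive: the exact test is undefined otherwise")
  min(stats::fisher.test(table)$p.value, 1)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p-value when the combined sample size is at most
#' `exact_limit` and there are no ties; otherwise the normal
#' approximation with tie correction (and continuity correction).
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_limit combined-n bound below which the exact distribution
#'   is used (default 50).
#' @return the two-sided p-value.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 50L) {
  if (!length(x) || !length(y)) stop_("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= exact_limit) && !ties
  p <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  if (is.nan(p)) p <- 1       # zero rank variance: completely tied samples
  p
}

#' Baseline-characteristics comparison table
#'
#' Compares the two arms of a cohort variable by variable: continuous
#' variables are summarized as median (IQR) per arm and compared with the
#' Mann-Whitney test; binary categorical variables as count (proportion)
#' per level and compared with the exact Fisher test. Proportions within
#' a variable and arm sum to 1.
#'
#' @param cohort a [trial_cohort()] containing both arms.
#' @param variables character vector of record columns to compare
#'   (default: age, sex, ecog, eod, pi). Biomarker columns are allowed
#'   and treated as continuous.
#' @return a `baseline_summary` data.frame with columns `variable`,
#'   `level`, `control`, `treatment`, `p_value` (the p-value appears on
#'   a variable's first row only). Write it with [utils::write.csv()] or
#'   [jsonlite::write_json()].
#' @export
baseline_table <- function(cohort,
                           variables = c("age", "sex", "ecog", "eod", "pi")) {
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown))
    stop_("unknown variable(s): %s", paste(unknown, collapse = ", "))
  ctrl <- cohort$arm == "control"
  trt <- cohort$arm == "treatment"
  if (!any(ctrl) || !any(trt))
    stop_("both arms must be present for a two-group comparison")

  rows <- list()
  for (v in variables) {
    val <- cohort[[v]]
    if (all(val %in% c(0, 1))) {
      tab <- rbind(c(sum(val[ctrl] == 1), sum(val[ctrl] == 0)),
                   c(sum(val[trt] == 1), sum(val[trt] == 0)))
      p <- fisher_exact_2x2(tab)
      for (lev in c(1, 0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = as.character(lev),
          control = sprintf("%d (%.1f%%)", sum(val[ctrl] == lev),
                            100 * mean(val[ctrl] == lev)),
          treatment = sprintf("%d (%.1f%%)", sum(val[trt] == lev),
                              100 * mean(val[trt] == lev)),
          p_value = if (lev == 1) p else NA_real_,
          stringsAsFactors = FALSE)
      }
    } else {
      p <- mann_whitney_u(val[ctrl], val[trt])
      fmt <- function(z) sprintf("%.3f (%.3f-%.3f)", stats::median(z),
                                 stats::quantile(z, 0.25), stats::quantile(z, 0.75))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "med (IQR)",
        control = fmt(val[ctrl]), treatment = fmt(val[trt]),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("baseline_summary", "data.frame")
  out
}

#' @export
print.baseline_summary <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$p_value <- ifelse(is.na(y$p_value), "", formatC(y$p_value, digits = digits,
                                                    format = "f"))
  print(y, row.names = FALSE)
  invisible(x)
}
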