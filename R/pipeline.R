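#' Pipeline configuration
#'
#' Exactly one of `cohort_path` (CSV in the documented schema) or `sim`
#' (a [sim_config()]) supplies the cohort.
#'
#' @param cohort_path path to a cohort CSV, or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param covariates baseline covariates screened in the Cox stage.
#' @param markers biomarkers to test (default: all marker columns).
#' @param chart a [chart_config()].
#' @param bootstrap_B bootstrap replicates for stability assessment.
#' @param out_dir output directory (created if needed).
#' @param seed global seed; expanded into per-stage substreams.
#' @param stages stages to run, a subset of the default vector (stage
#'   order is fixed; later stages reuse earlier in-memory results).
#' @param subset optional sensitivity filter, a list with any of
#'   `sex` (0/1), `age_min`, `age_max`; applied before all stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, sim = NULL,
                            covariates = c("age", "sex", "ecog", "eod", "pi"),
                            markers = NULL, chart = chart_config(),
                            bootstrap_B = 200L, out_dir = "raes-output",
                            seed = 1L,
                            stages = c("simulate", "baseline", "cox", "chart",
                                       "cutpoints", "interactions",
                                       "bootstrap", "subgroup_charts"),
                            subset = NULL) {
  if (is.null(cohort_path) == is.null(sim))
    stop_("exactly one of cohort_path or sim must be given")
  structure(list(cohort_path = cohort_path, sim = sim,
                 covariates = covariates, markers = markers, chart = chart,
                 bootstrap_B = as.integer(bootstrap_B), out_dir = out_dir,
                 seed = seed, stages = stages, subset = subset),
            class = "pipeline_config")
}

#' Run the full monitoring and biomarker pipeline
#'
#' Stages, in order: acquire the cohort (simulate or read), baseline
#' comparison table, Cox screening (univariate per covariate plus the
#' multivariable model with Benjamini-Hochberg-adjusted p-values),
#' global risk-adjusted EWMA chart (Phase I on the control arm, limits
#' calibrated by Monte Carlo, treatment arm monitored), maximally
#' selected cut-points per marker, interaction models, bootstrap
#' stability for markers with a significant interaction, and
#' subgroup-level charts for those markers. Each stage writes a CSV
#' under `out_dir` and is recorded, with the seed it consumed, in
#' `manifest.json`. A failing stage aborts with its name; files already
#' written are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  env$manifest <- list(seed = config$seed, stages = list())
  results <- list()
  record <- function(stage, file, seed = NULL) {
    env$manifest$stages[[stage]] <- list(file = file, seed = seed)
    jsonlite::write_json(env$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  want <- function(stage) stage %in% config$stages
  guard <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_("stage '%s' failed: %s (partial outputs kept in %s)",
            stage, conditionMessage(e), config$out_dir))
  }

  # -- cohort acquisition ----------------------------------------------
  if (!is.null(config$sim)) {
    if (want("simulate")) {
      results$cohort <- guard("simulate", {
        sim <- config$sim
        sim$seed <- sim$seed %||% substream_seed(config$seed, 101L)
        cohort <- simulate_cohort(sim)
        write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
        record("simulate", "cohort.csv", sim$seed)
        cohort
      })
    } else {                                        # stage skipped: reuse file
      results$cohort <- read_cohort(file.path(config$out_dir, "cohort.csv"))
    }
  } else {
    results$cohort <- read_cohort(config$cohort_path)
  }
  cohort <- results$cohort
  if (!is.null(config$subset)) {
    s <- config$subset
    keep <- rep(TRUE, nrow(cohort))
    if (!is.null(s$sex)) keep <- keep & cohort$sex == s$sex
    if (!is.null(s$age_min)) keep <- keep & cohort$age > s$age_min
    if (!is.null(s$age_max)) keep <- keep & cohort$age <= s$age_max
    cohort <- cohort[keep, , drop = FALSE]
    results$cohort <- cohort
  }
  markers <- config$markers %||% marker_names(cohort)
  ctrl <- cohort[cohort$arm == "control", , drop = FALSE]
  test <- cohort[cohort$arm == "treatment", , drop = FALSE]

  if (want("baseline")) results$baseline <- guard("baseline", {
    bt <- baseline_table(cohort, config$covariates)
    utils::write.csv(bt, file.path(config$out_dir, "baseline.csv"),
                     row.names = FALSE)
    record("baseline", "baseline.csv")
    bt
  })

  if (want("cox")) results$cox <- guard("cox", {
    uni <- do.call(rbind, lapply(config$covariates, function(v)
      summary(fit_cox(cohort, v))))
    names(uni) <- paste0("uni_", names(uni))
    multi <- summary(fit_cox(cohort, config$covariates), bh = TRUE)
    tab <- cbind(covariate = multi$covariate,
                 uni[c("uni_hr", "uni_hr_low", "uni_hr_high", "uni_p")],
                 multi[c("hr", "hr_low", "hr_high", "p", "p_adj")])
    utils::write.csv(tab, file.path(config$out_dir, "cox_screen.csv"),
                     row.names = FALSE)
    record("cox", "cox_screen.csv")
    tab
  })

  phase1_covs <- if (!is.null(results$cox)) {
    sig <- results$cox$covariate[results$cox$p_adj < 0.05]
    if (length(sig)) sig else config$covariates
  } else intersect(c("ecog", "eod", "pi"), config$covariates)

  if (want("chart")) results$chart <- guard("chart", {
    fit <- fit_cox(ctrl, phase1_covs)
    cfg <- config$chart
    cfg$seed <- cfg$seed %||% substream_seed(config$seed, 102L)
    lim <- calibrate_limits(fit, ctrl, nrow(test), cfg)
    ch <- monitor_sequence(test, fit, lim, cfg)
    utils::write.csv(ch$series, file.path(config$out_dir, "chart_series.csv"),
                     row.names = FALSE)
    results$phase1_fit <- fit
    record("chart", "chart_series.csv", cfg$seed)
    ch
  })

  if (want("cutpoints")) results$cutpoints <- guard("cutpoints", {
    cps <- lapply(markers, function(m) max_logrank_cutpoint(cohort, m))
    names(cps) <- markers
    tab <- data.frame(marker = markers,
                      cutpoint = vapply(cps, `[[`, 0, "cutpoint"),
                      statistic = vapply(cps, `[[`, 0, "statistic"))
    utils::write.csv(tab, file.path(config$out_dir, "cutpoints.csv"),
                     row.names = FALSE)
    record("cutpoints", "cutpoints.csv")
    cps
  })

  if (want("interactions")) results$interactions <- guard("interactions", {
    if (is.null(results$cutpoints)) stop_("requires the cutpoints stage")
    ir <- lapply(results$cutpoints, function(cp)
      interaction_cox(cohort, cp$marker, cp$cutpoint))
    tab <- do.call(rbind, lapply(ir, function(x) data.frame(
      marker = x$marker, cutpoint = x$cutpoint,
      interaction_hr = x$interaction_hr,
      ci_low = x$ci[1], ci_high = x$ci[2], p = x$p,
      hr_low_class = x$subgroup$low$hr, p_low_class = x$subgroup$low$p,
      hr_high_class = x$subgroup$high$hr, p_high_class = x$subgroup$high$p,
      median_trt_low = x$subgroup$low$median_treatment,
      median_ctrl_low = x$subgroup$low$median_control,
      median_trt_high = x$subgroup$high$median_treatment,
      median_ctrl_high = x$subgroup$high$median_control)))
    utils::write.csv(tab, file.path(config$out_dir, "interactions.csv"),
                     row.names = FALSE)
    record("interactions", "interactions.csv")
    ir
  })

  sig_markers <- if (!is.null(results$interactions)) {
    ps <- vapply(results$interactions, `[[`, 0, "p")
    names(ps)[ps < 0.05]
  } else character(0)

  if (want("bootstrap")) results$bootstrap <- guard("bootstrap", {
    if (is.null(results$interactions)) stop_("requires the interactions stage")
    bseed <- substream_seed(config$seed, 103L)
    rows <- lapply(sig_markers, function(m) {
      bs <- bootstrap_cutpoint_stability(
        cohort, m, results$cutpoints[[m]]$cutpoint,
        B = config$bootstrap_B, seed = substream_seed(bseed, 1L, match(m, markers)))
      data.frame(marker = m, proportion = bs$proportion,
                 n_used = bs$n_used, n_skipped = bs$n_skipped, B = bs$B)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(marker = character(0), proportion = numeric(0),
                 n_used = integer(0), n_skipped = integer(0), B = integer(0))
    utils::write.csv(tab, file.path(config$out_dir, "bootstrap.csv"),
                     row.names = FALSE)
    record("bootstrap", "bootstrap.csv", bseed)
    tab
  })

  if (want("subgroup_charts")) results$subgroup_charts <- guard("subgroup_charts", {
    if (is.null(results$interactions)) stop_("requires the interactions stage")
    sseed <- substream_seed(config$seed, 104L)
    rows <- list()
    charts <- list()
    for (m in sig_markers) {
      cfg <- config$chart
      cfg$seed <- substream_seed(sseed, 2L, match(m, markers))
      sc <- tryCatch(
        subgroup_charts(cohort, m, results$cutpoints[[m]]$cutpoint, cfg,
                        covariates = phase1_covs),
        error = function(e) NULL)
      if (is.null(sc)) next
      for (cls in names(sc)) {
        sm <- summary(sc[[cls]])
        rows[[paste(m, cls)]] <- cbind(marker = m, class = cls, sm)
      }
      charts[[m]] <- sc
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(marker = character(0), class = character(0))
    utils::write.csv(tab, file.path(config$out_dir, "subgroup_signals.csv"),
                     row.names = FALSE)
    record("subgroup_charts", "subgroup_signals.csv", sseed)
    charts
  })

  results$manifest <- env$manifest
  invisible(results)
}
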