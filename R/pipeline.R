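#' Pipeline configuration
#'
#' Bundles and validates every analysis choice of the end-to-end pipeline;
#' the validated configuration is echoed verbatim into every report for
#' provenance.
#'
#' @param width_scans segment width in scans (default 30).
#' @param aggregate within-segment aggregation, `"sum"` or `"mean"`.
#' @param n_reps permutation repetitions for the Monte-Carlo null.
#' @param seed master seed for all pipeline randomness.
#' @param grid_step accuracy-grid spacing of the rank-abundance curves.
#' @param max_gap merge gap for adjacent-signal correction.
#' @param loo run leave-one-out cross-validation (`TRUE`/`FALSE`).
#' @param scan_rate scans per minute assumed when reading chromatograms.
#' @return a validated object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(width_scans = 30L, aggregate = c("sum", "mean"),
                            n_reps = 40L, seed = 1L, grid_step = 0.005,
                            max_gap = 1L, loo = TRUE, scan_rate = 3013) {
  aggregate <- match.arg(aggregate)
  cfg <- list(width_scans = as.integer(width_scans), aggregate = aggregate,
              n_reps = as.integer(n_reps), seed = as.integer(seed),
              grid_step = as.numeric(grid_step), max_gap = as.integer(max_gap),
              loo = isTRUE(loo), scan_rate = as.numeric(scan_rate))
  if (cfg$width_scans < 1L) stop("width_scans must be >= 1")
  if (cfg$n_reps < 1L) stop("n_reps must be >= 1")
  if (cfg$grid_step <= 0 || cfg$grid_step > 0.5) stop("grid_step must be in (0, 0.5]")
  if (cfg$max_gap < 0L) stop("max_gap must be >= 0")
  if (cfg$scan_rate <= 0) stop("scan_rate must be > 0")
  structure(cfg, class = "pipeline_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full breath-biomarker pipeline on a cohort
#'
#' Executes, in order: cohort reading, segmentation and alveolar-gradient
#' computation, permutation-null biomarker discovery with adjacent-signal
#' merging, WDA fitting, resubstitution ROC, and (optionally) exhaustive
#' leave-one-out cross-validation. The pipeline is a pure function of the
#' cohort, the configuration and the seed; a report produced twice from the
#' same inputs is byte-identical.
#'
#' @param cohort path to a cohort manifest CSV (see [read_cohort()]) or a
#'   list of [subject_record()] objects.
#' @param config a [pipeline_config()].
#' @param out optional path: write the report as JSON (plus
#'   `<out>.curves.tsv` and `<out>.roc.tsv` side files for plotting).
#' @param verbose log stage-by-stage progress via [message()].
#' @return object of class `"analysis_report"` (list): `config`, `n_subjects`,
#'   `n_disease`, `n_control`, `n_segments`, `discovery` (threshold, excess,
#'   selected segments, merged peaks), `wda` (rules), `resub` and `loo`
#'   (AUC + operating point + scores), `version`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  records <- pipeline_stage("read_cohort", {
    if (is.character(cohort)) read_cohort(cohort, scan_rate = config$scan_rate)
    else cohort
  })
  say(length(records), " subjects read")
  gm <- pipeline_stage("gradients", {
    scheme <- segment_scheme(length(records[[1L]]$breath$response),
                             config$width_scans)
    cohort_gradients(records, scheme, aggregate = config$aggregate)
  })
  say(ncol(gm$gradients), " segments per subject")
  disc <- pipeline_stage("discovery",
    discover_biomarkers(gm, n_reps = config$n_reps, seed = config$seed,
                        grid_step = config$grid_step,
                        max_gap = config$max_gap))
  say(nrow(disc$selected), " segments selected -> ", nrow(disc$merged),
      " merged biomarker peak(s)")
  has_biomarkers <- nrow(disc$merged) > 0L
  model <- if (has_biomarkers)
    pipeline_stage("wda", fit_wda(gm, disc$merged)) else NULL
  resub_scores <- if (has_biomarkers) wda_scores(model, gm)
    else rep(0, nrow(gm$gradients))
  resub_roc <- pipeline_stage("resubstitution",
                              roc_curve(resub_scores, gm$labels))
  say(sprintf("resubstitution AUC %.3f", resub_roc$auc))
  loo <- NULL
  if (config$loo) {
    loo <- pipeline_stage("loo",
      loo_cross_validate(gm, n_reps = config$n_reps, seed = config$seed,
                         grid_step = config$grid_step,
                         max_gap = config$max_gap))
    say(sprintf("LOO AUC %.3f", loo$roc$auc))
  }
  report <- structure(
    list(config = unclass(config),
         version = as.character(utils::packageVersion("breathmark")),
         n_subjects = length(records),
         n_disease = sum(gm$labels == "disease"),
         n_control = sum(gm$labels == "control"),
         n_segments = ncol(gm$gradients),
         discovery = list(threshold = disc$threshold,
                          excess_count = disc$excess_count,
                          selected_segments = disc$selected$segment,
                          merged_peaks = disc$merged),
         wda = if (has_biomarkers)
           list(rules = model$rules, sum_weights = model$sum_weights)
           else NULL,
         resub = list(
           auc = resub_roc$auc,
           operating_point = optimal_operating_point(resub_roc),
           scores = data.frame(subject_id = gm$subject_ids,
                               label = gm$labels, score = resub_scores,
                               stringsAsFactors = FALSE)),
         loo = if (!is.null(loo)) list(
           auc = loo$roc$auc,
           operating_point = optimal_operating_point(loo$roc),
           scores = loo$scores) else NULL),
    class = "analysis_report")
  report$internals <- list(gm = gm, discovery = disc, model = model,
                           resub_roc = resub_roc, loo = loo)
  if (!is.null(out)) write_report(report, out, disc, resub_roc, loo)
  report
}

# JSON report + TSV side files; `internals` (full R objects) never
# serialized, so reports are plain reviewable text.
write_report <- function(report, out, disc, resub_roc, loo) {
  obj <- unclass(report)
  obj$internals <- NULL
  # -Inf/Inf thresholds are not valid JSON numbers; stringify operating points
  fix_op <- function(op) { op$threshold <- as.character(op$threshold); op }
  obj$resub$operating_point <- fix_op(obj$resub$operating_point)
  if (!is.null(obj$loo)) obj$loo$operating_point <- fix_op(obj$loo$operating_point)
  jsonlite::write_json(obj, out, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", null = "null")
  utils::write.table(disc$curves$curves, paste0(out, ".curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  roc_tab <- resub_roc$points
  roc_tab$which <- "resubstitution"
  if (!is.null(loo)) {
    lt <- loo$roc$points; lt$which <- "loo"
    roc_tab <- rbind(roc_tab, lt)
  }
  utils::write.table(roc_tab, paste0(out, ".roc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d subjects (%d disease / %d control), %d segments\n",
              x$n_subjects, x$n_disease, x$n_control, x$n_segments))
  cat(sprintf("  discovery: threshold %s, %d selected segment(s), %d merged peak(s), excess %.2f\n",
              if (is.na(x$discovery$threshold)) "none"
              else format(x$discovery$threshold),
              length(x$discovery$selected_segments),
              nrow(x$discovery$merged_peaks), x$discovery$excess_count))
  op <- x$resub$operating_point
  cat(sprintf("  resubstitution: AUC %.3f; sens %.3f / spec %.3f\n",
              x$resub$auc, op$sensitivity, op$specificity))
  if (!is.null(x$loo)) {
    op <- x$loo$operating_point
    cat(sprintf("  leave-one-out:  AUC %.3f; sens %.3f / spec %.3f\n",
                x$loo$auc, op$sensitivity, op$specificity))
  }
  invisible(x)
}

#' Chain a pipeline report into a screening projection
#'
#' Takes the validated operating point of an analysis report (LOO if
#' available, else resubstitution) — or explicit sensitivity/specificity —
#' and projects expected outcomes onto a screened population.
#'
#' @param report an [run_pipeline()] report, or `NULL` when `sensitivity`
#'   and `specificity` are given explicitly.
#' @param prevalence,population see [project_screening()].
#' @param sensitivity,specificity explicit operating point (proportions);
#'   override the report when non-`NULL`.
#' @param use `"loo"` or `"resub"`: which operating point to take from the
#'   report.
#' @return a [project_screening()] result.
#' @export
run_projection <- function(report = NULL, prevalence, population,
                           sensitivity = NULL, specificity = NULL,
                           use = c("loo", "resub")) {
  use <- match.arg(use)
  if (is.null(sensitivity) != is.null(specificity))
    stop("provide both sensitivity and specificity, or neither")
  if (is.null(sensitivity)) {
    if (is.null(report)) stop("need a report or an explicit operating point")
    src <- if (use == "loo" && !is.null(report$loo)) report$loo else report$resub
    if (is.null(src$operating_point)) stop("report carries no operating point")
    sensitivity <- src$operating_point$sensitivity
    specificity <- src$operating_point$specificity
  }
  project_screening(sensitivity, specificity, prevalence, population)
}
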