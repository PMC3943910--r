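#' Empirical ROC curve of a score vector
#'
#' Builds the empirical ROC over all distinct score thresholds (positive
#' call: score at or above the threshold), including the trivial endpoints
#' `(sensitivity, specificity) = (1, 0)` and `(0, 1)`. The trapezoidal AUC
#' equals the Mann-Whitney C-statistic of the scores exactly.
#'
#' @param scores numeric discriminant values, one per subject.
#' @param labels matching `"disease"` / `"control"` labels.
#' @return object of class `"breath_roc"`: data frame `points` with columns
#'   `threshold`, `sensitivity`, `specificity`, plus `auc`, `n_disease`,
#'   `n_control`.
#' @export
roc_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(labels))
  is_d <- labels == "disease"
  nd <- sum(is_d); nc <- sum(!is_d)
  if (nd == 0L || nc == 0L) stop("both classes must be present")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[is_d] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!is_d] < t), numeric(1))
  # trapezoid over (FPR, TPR); thresholds ascend so FPR descends 1 -> 0
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1L]) *
             (sens[-length(sens)] + sens[-1L]) / 2)
  structure(
    list(points = data.frame(threshold = thr, sensitivity = sens,
                             specificity = spec),
         auc = auc, n_disease = nd, n_control = nc),
    class = "breath_roc")
}

#' @export
print.breath_roc <- function(x, ...) {
  op <- optimal_operating_point(x)
  cat(sprintf("<breath_roc> AUC %.3f (%d disease / %d control); best operating point: sens %.3f, spec %.3f at threshold %s\n",
              x$auc, x$n_disease, x$n_control,
              op$sensitivity, op$specificity, format(op$threshold)))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x a `"breath_roc"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.breath_roc <- function(x, ...) {
  graphics::plot(1 - x$points$specificity, x$points$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Operating point maximising sensitivity + specificity
#'
#' Returns the ROC point where the sum of sensitivity and specificity
#' (equivalently the Youden index) is maximal; ties resolve to the higher
#' sensitivity, then to the lower threshold.
#'
#' @param roc a [roc_curve()] result.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_operating_point <- function(roc) {
  stopifnot(inherits(roc, "breath_roc"))
  p <- roc$points
  s <- p$sensitivity + p$specificity
  ord <- order(-s, -p$sensitivity, p$threshold)
  i <- ord[1L]
  list(threshold = p$threshold[i], sensitivity = p$sensitivity[i],
       specificity = p$specificity[i])
}

#' Exhaustive leave-one-out cross-validation of the full pipeline
#'
#' One subject at a time is removed; the remaining subjects are used to
#' re-derive the whole algorithm — permutation-null biomarker discovery,
#' adjacent-signal merging, and WDA fitting — and the held-out subject's
#' discriminant value is computed from that fold's model. All out-of-sample
#' scores are pooled into one ROC curve. Fold seeds derive deterministically
#' from the master seed and the held-out subject's id, so results do not
#' depend on subject order. A fold whose biomarker selection is empty scores
#' its held-out subject 0 with a warning rather than failing.
#'
#' @param gm a [gradient_matrix()] with at least 3 subjects per class.
#' @param n_reps permutation repetitions per fold (default 40).
#' @param seed master seed.
#' @param grid_step,max_gap passed to [discover_biomarkers()].
#' @return object of class `"loo_result"`: data frame `scores` (one
#'   out-of-sample row per subject: `subject_id`, `label`, `score`,
#'   `n_biomarkers`), pooled `roc`, and `folds` (per-fold biomarker counts
#'   and thresholds).
#' @export
loo_cross_validate <- function(gm, n_reps = 40L, seed = 1L,
                               grid_step = 0.005, max_gap = 1L) {
  stopifnot(inherits(gm, "gradient_matrix"))
  check_two_classes(gm$labels, min_per_class = 3L)
  n <- nrow(gm$gradients)
  score <- numeric(n); n_bio <- integer(n); thr <- numeric(n)
  for (i in seq_len(n)) {
    sub <- structure(
      list(gradients = gm$gradients[-i, , drop = FALSE],
           labels = gm$labels[-i], subject_ids = gm$subject_ids[-i],
           aggregate = gm$aggregate),
      class = "gradient_matrix")
    fold_seed <- derive_seed(seed, gm$subject_ids[i])
    disc <- withCallingHandlers(
      discover_biomarkers(sub, n_reps = n_reps, seed = fold_seed,
                          grid_step = grid_step, max_gap = max_gap),
      warning = function(w) invokeRestart("muffleWarning"))
    n_bio[i] <- nrow(disc$merged)
    thr[i] <- disc$threshold
    if (n_bio[i] == 0L) {
      warning("LOO fold for subject ", gm$subject_ids[i],
              ": empty biomarker selection; held-out score set to 0",
              call. = FALSE)
      score[i] <- 0
    } else {
      model <- fit_wda(sub, disc$merged)
      score[i] <- wda_score(model, gm$gradients[i, ])
    }
  }
  structure(
    list(scores = data.frame(subject_id = gm$subject_ids, label = gm$labels,
                             score = score, n_biomarkers = n_bio,
                             stringsAsFactors = FALSE),
         roc = roc_curve(score, gm$labels),
         folds = data.frame(subject_id = gm$subject_ids,
                            n_biomarkers = n_bio, threshold = thr,
                            stringsAsFactors = FALSE)),
    class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d out-of-sample scores; pooled AUC %.3f; %d fold(s) with empty selection\n",
              nrow(x$scores), x$roc$auc, sum(x$scores$n_biomarkers == 0)))
  invisible(x)
}

#' Resubstitution-versus-LOO accuracy report
#'
#' @param resub_roc ROC of in-sample (resubstitution) scores.
#' @param loo_roc ROC of pooled leave-one-out scores.
#' @return list with `resub_auc`, `loo_auc`, and the operating point
#'   (threshold, sensitivity, specificity) of each curve.
#' @export
accuracy_report <- function(resub_roc, loo_roc) {
  stopifnot(inherits(resub_roc, "breath_roc"), inherits(loo_roc, "breath_roc"))
  list(resub_auc = resub_roc$auc,
       loo_auc = loo_roc$auc,
       resub_operating_point = optimal_operating_point(resub_roc),
       loo_operating_point = optimal_operating_point(loo_roc))
}
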