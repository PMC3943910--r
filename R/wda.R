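#' Fit a weighted digital analysis (WDA) classifier
#'
#' WDA sums, over the selected biomarkers, a weight times a binary indicator
#' of whether the subject's alveolar gradient lies on the disease side of a
#' marker-specific cutoff. The source method is cited without formulas in
#' the breath-test literature, so this implementation fixes a reconstruction
#' (documented as such): for each biomarker segment the cutoff is chosen
#' among midpoints of the sorted training gradients to maximise the Youden
#' index (sensitivity + specificity - 1) of that single marker, the disease
#' side is the side with the higher disease density (from the sign of
#' `AUC - 0.5`, ties counting as disease-higher), and the weight is the
#' marker's Gini coefficient `2 * folded AUC - 1`, hence in `[0, 1]`.
#' Cutoff ties resolve to the smallest cutoff value.
#'
#' @param gm a [gradient_matrix()] of training subjects.
#' @param biomarkers biomarker segments: an integer vector of segment
#'   indices, or a merged-peak table from [merge_adjacent()] (its
#'   `representative` column is used).
#' @return object of class `"wda_model"`: data frame `rules` with columns
#'   `segment`, `cutoff`, `direction`, `weight`, plus `n_segments`,
#'   `sum_weights`, and training metadata (`n_disease`, `n_control`,
#'   `aggregate`).
#' @export
fit_wda <- function(gm, biomarkers) {
  stopifnot(inherits(gm, "gradient_matrix"))
  if (is.data.frame(biomarkers)) biomarkers <- biomarkers$representative
  biomarkers <- as.integer(biomarkers)
  if (length(biomarkers) == 0L) stop("no biomarkers selected")
  if (anyDuplicated(biomarkers)) stop("biomarker segments must be unique")
  if (any(biomarkers < 1L | biomarkers > ncol(gm$gradients)))
    stop("biomarker segment index outside the gradient matrix")
  check_two_classes(gm$labels, min_per_class = 1L)
  is_d <- gm$labels == "disease"
  rules <- do.call(rbind, lapply(biomarkers, function(s) {
    g <- gm$gradients[, s]
    fit_rule(g[is_d], g[!is_d], s)
  }))
  structure(
    list(rules = rules,
         n_segments = ncol(gm$gradients),
         sum_weights = sum(rules$weight),
         n_disease = sum(is_d), n_control = sum(!is_d),
         aggregate = gm$aggregate),
    class = "wda_model")
}

# Single-marker rule: Youden-optimal midpoint cutoff, direction from AUC,
# weight = 2*folded_auc - 1. Boundary (value == cutoff) is disease-like.
fit_rule <- function(d, c, segment) {
  auc <- c_statistic(d, c)
  direction <- if (auc >= 0.5) "disease_higher" else "disease_lower"
  u <- sort(unique(c(d, c)))
  cand <- if (length(u) >= 2L) (u[-length(u)] + u[-1L]) / 2 else u
  youden <- vapply(cand, function(cut) {
    if (direction == "disease_higher")
      mean(d >= cut) + mean(c < cut) - 1
    else
      mean(d <= cut) + mean(c > cut) - 1
  }, numeric(1))
  best <- which(youden == max(youden))[1L]  # smallest cutoff on ties
  data.frame(segment = as.integer(segment), cutoff = cand[best],
             direction = direction, weight = 2 * fold_auc(auc) - 1,
             stringsAsFactors = FALSE)
}

#' @export
print.wda_model <- function(x, ...) {
  cat(sprintf("<wda_model> %d rule(s), total weight %.3f (trained on %d disease / %d control)\n",
              nrow(x$rules), x$sum_weights, x$n_disease, x$n_control))
  print(x$rules, row.names = FALSE)
  invisible(x)
}

#' WDA discriminant score of a subject
#'
#' Sums `weight * digital` over the model's rules, where `digital` is 1 when
#' the subject's gradient lies on the disease side of the rule's cutoff
#' (a gradient exactly at the cutoff counts as disease-like). The score is
#' bounded by `[0, sum of weights]`.
#'
#' @param model a [fit_wda()] model.
#' @param profile a [alveolar_gradients()] profile, or a bare numeric vector
#'   of per-segment gradients, from the model's segment scheme.
#' @return the discriminant value (single number).
#' @export
wda_score <- function(model, profile) {
  stopifnot(inherits(model, "wda_model"))
  g <- if (inherits(profile, "gradient_profile")) profile$gradients
       else as.numeric(profile)
  if (length(g) != model$n_segments)
    stop("profile has ", length(g), " segments but the model was trained on ",
         model$n_segments, "; segment schemes differ")
  r <- model$rules
  v <- g[r$segment]
  digital <- ifelse(r$direction == "disease_higher", v >= r$cutoff, v <= r$cutoff)
  sum(r$weight * digital)
}

#' WDA scores for every row of a gradient matrix
#'
#' @param model a [fit_wda()] model.
#' @param gm a [gradient_matrix()] with the model's segment count.
#' @return numeric vector of discriminant values, one per subject.
#' @export
wda_scores <- function(model, gm) {
  stopifnot(inherits(gm, "gradient_matrix"))
  apply(gm$gradients, 1, function(g) wda_score(model, g))
}

#' Classify a subject from its WDA score
#'
#' @param model a [fit_wda()] model.
#' @param profile gradient profile or numeric vector (see [wda_score()]).
#' @param threshold decision threshold in `[0, sum of weights]`; scores at
#'   or above it are called positive.
#' @return `"positive"` or `"negative"`.
#' @export
classify <- function(model, profile, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (wda_score(model, profile) >= threshold) "positive" else "negative"
}

#' Serialize a WDA model to JSON
#'
#' @param model a [fit_wda()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wda_model <- function(model, path) {
  stopifnot(inherits(model, "wda_model"))
  obj <- list(schema = "breathmark/wda_model/v1",
              rules = model$rules,
              n_segments = model$n_segments,
              sum_weights = model$sum_weights,
              n_disease = model$n_disease, n_control = model$n_control,
              aggregate = model$aggregate)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Read a WDA model serialized by [write_wda_model()]
#'
#' @param path JSON path.
#' @return a `"wda_model"`.
#' @export
read_wda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "breathmark/wda_model/v1"))
    stop("not a breathmark WDA model file: ", path)
  structure(
    list(rules = as.data.frame(obj$rules),
         n_segments = as.integer(obj$n_segments),
         sum_weights = as.numeric(obj$sum_weights),
         n_disease = as.integer(obj$n_disease),
         n_control = as.integer(obj$n_control),
         aggregate = obj$aggregate),
    class = "wda_model")
}
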