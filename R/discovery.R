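#' Stack gradient profiles into a subjects-by-segments matrix
#'
#' @param profiles list of [alveolar_gradients()] results, one per subject,
#'   all from the same segment scheme and aggregate.
#' @return an object of class `"gradient_matrix"`: `gradients` (numeric
#'   matrix, subjects in rows), `labels` (character, `"disease"`/`"control"`),
#'   `subject_ids`, `aggregate`.
#' @export
gradient_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "gradient_profile")))
  lens <- vapply(profiles, function(p) length(p$gradients), integer(1))
  if (length(unique(lens)) != 1L)
    stop("gradient profiles have differing segment counts; ",
         "all subjects must share one segment scheme")
  g <- do.call(rbind, lapply(profiles, `[[`, "gradients"))
  structure(
    list(gradients = g,
         labels = vapply(profiles, `[[`, character(1), "label"),
         subject_ids = vapply(profiles, `[[`, character(1), "subject_id"),
         aggregate = profiles[[1L]]$aggregate),
    class = "gradient_matrix")
}

#' Compute the gradient matrix of a cohort
#'
#' Convenience wrapper: segments every record and stacks the per-subject
#' alveolar gradients.
#'
#' @param records list of [subject_record()].
#' @param scheme a [segment_scheme()]; defaults to the 30-scan tiling of the
#'   first record's scan count.
#' @param aggregate `"sum"` or `"mean"` (see [alveolar_gradients()]).
#' @return a `"gradient_matrix"`.
#' @export
cohort_gradients <- function(records, scheme = NULL,
                             aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(records) >= 1L)
  if (is.null(scheme))
    scheme <- segment_scheme(length(records[[1L]]$breath$response))
  gm <- gradient_matrix(lapply(records, alveolar_gradients,
                               scheme = scheme, aggregate = aggregate))
  gm$scheme <- scheme
  gm
}

check_two_classes <- function(labels, min_per_class = 2L) {
  nd <- sum(labels == "disease"); nc <- sum(labels == "control")
  if (nd < min_per_class || nc < min_per_class)
    stop("need at least ", min_per_class,
         " subjects per class (got disease=", nd, ", control=", nc, ")")
  invisible(c(disease = nd, control = nc))
}

#' C-statistic (ROC AUC) of one candidate marker
#'
#' Mann-Whitney pair-counting definition: the probability that a randomly
#' chosen disease value exceeds a randomly chosen control value, counting
#' ties as one half. Equals the trapezoidal area under the empirical ROC
#' curve exactly.
#'
#' @param disease_values,control_values numeric vectors (non-empty, finite).
#' @return the AUC in `[0, 1]`.
#' @export
c_statistic <- function(disease_values, control_values) {
  nd <- length(disease_values); nc <- length(control_values)
  if (nd == 0L || nc == 0L) stop("both groups must be non-empty")
  v <- c(disease_values, control_values)
  if (!all(is.finite(v))) stop("values must be finite")
  r <- rank(v)  # midranks: encodes wins + ties/2 exactly
  (sum(r[seq_len(nd)]) - nd * (nd + 1) / 2) / (nd * nc)
}

# Folded AUCs of every column of X for the disease-row subset, via midranks
# computed once. `R` is the precomputed rank matrix apply(X, 2, rank).
fold_auc <- function(auc) pmax(auc, 1 - auc)

column_aucs <- function(R, disease_rows, nd, nc) {
  s <- if (nd == 1L) R[disease_rows, ] else colSums(R[disease_rows, , drop = FALSE])
  (s - nd * (nd + 1) / 2) / (nd * nc)
}

#' Score every segment as a candidate biomarker
#'
#' Computes the C-statistic of each segment's alveolar gradients between the
#' disease and control groups. The folded AUC `max(AUC, 1 - AUC)` measures
#' accuracy irrespective of effect direction (both elevated and depressed
#' gradients are candidate biomarkers); the direction is retained for the
#' WDA classifier. Ranking is by folded AUC descending, ties broken by lower
#' segment index.
#'
#' @param gm a [gradient_matrix()].
#' @return data frame with one row per segment (in segment order): `segment`,
#'   `auc`, `folded_auc`, `direction` (`"disease_higher"` / `"disease_lower"`,
#'   tie counts as higher), `rank`.
#' @export
score_segments <- function(gm) {
  stopifnot(inherits(gm, "gradient_matrix"))
  check_two_classes(gm$labels)
  X <- gm$gradients
  R <- apply(X, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, nrow = nrow(X))
  nd <- sum(gm$labels == "disease"); nc <- sum(gm$labels == "control")
  auc <- column_aucs(R, gm$labels == "disease", nd, nc)
  folded <- fold_auc(auc)
  out <- data.frame(
    segment = seq_along(auc),
    auc = auc,
    folded_auc = folded,
    direction = ifelse(auc >= 0.5, "disease_higher", "disease_lower"),
    stringsAsFactors = FALSE)
  out$rank <- rank_by_folded(out$folded_auc, out$segment)
  out
}

# Rank descending by folded AUC, tie -> lower segment index first.
rank_by_folded <- function(folded, segment) {
  ord <- order(-folded, segment)
  r <- integer(length(folded)); r[ord] <- seq_along(ord)
  r
}

#' Monte-Carlo permutation null of the per-segment folded AUCs
#'
#' Randomly permutes subjects between the disease and control groups
#' (preserving the group sizes) and recomputes every segment's folded AUC;
#' the default 40 repetitions match the instrument method's Monte-Carlo
#' protocol. One label permutation scores all segments, so the random
#' rank-abundance curve is internally coherent.
#'
#' @param gm a [gradient_matrix()].
#' @param n_reps number of random label assignments (default 40).
#' @param seed integer seed; the null is reproducible from it.
#' @return object of class `"permutation_null"`: `folded` (reps-by-segments
#'   matrix), `n_reps`, `seed`.
#' @export
permutation_null <- function(gm, n_reps = 40L, seed = 1L) {
  stopifnot(inherits(gm, "gradient_matrix"))
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  check_two_classes(gm$labels)
  X <- gm$gradients
  R <- apply(X, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, nrow = nrow(X))
  n <- nrow(X); nd <- sum(gm$labels == "disease"); nc <- n - nd
  set.seed(as.integer(seed))
  folded <- matrix(NA_real_, n_reps, ncol(X))
  for (b in seq_len(n_reps)) {
    rows <- sample.int(n, nd)
    folded[b, ] <- fold_auc(column_aucs(R, rows, nd, nc))
  }
  structure(list(folded = folded, n_reps = n_reps, seed = as.integer(seed)),
            class = "permutation_null")
}

#' Correct-versus-random rank-abundance curves
#'
#' For each accuracy level `x` on a grid over `[0.5, 1]`, counts the
#' candidate segments whose folded AUC reaches `x` under the true diagnosis
#' ("correct" curve) and, averaged over the permutation repetitions, under
#' random diagnosis ("random" curve). The horizontal separation of the two
#' curves reflects the amount of diagnostic information in the breath signal.
#'
#' @param scores output of [score_segments()].
#' @param null output of [permutation_null()] on the same gradient matrix.
#' @param grid_step accuracy-grid spacing (default 0.005).
#' @return object of class `"rank_abundance"`: data frame `curves` with
#'   columns `accuracy`, `correct_count`, `random_count`, plus `n_segments`.
#' @export
rank_abundance <- function(scores, null, grid_step = 0.005) {
  stopifnot(is.data.frame(scores), inherits(null, "permutation_null"))
  if (ncol(null$folded) != nrow(scores))
    stop("scores and null cover different segment sets (",
         nrow(scores), " vs ", ncol(null$folded), " segments)")
  grid <- seq(0.5, 1, by = grid_step)
  eps <- 1e-9  # guard against grid values sitting a float below a folded AUC
  correct <- vapply(grid, function(x) sum(scores$folded_auc >= x - eps),
                    numeric(1))
  random <- vapply(grid, function(x)
    mean(rowSums(null$folded >= x - eps)), numeric(1))
  structure(
    list(curves = data.frame(accuracy = grid, correct_count = correct,
                             random_count = random),
         n_segments = nrow(scores)),
    class = "rank_abundance")
}

#' @export
print.rank_abundance <- function(x, ...) {
  cat(sprintf("<rank_abundance> %d segments; correct curve reaches %.3f, random %.3f at accuracy 1\n",
              x$n_segments, utils::tail(x$curves$correct_count, 1),
              utils::tail(x$curves$random_count, 1)))
  invisible(x)
}

#' Plot correct-versus-random rank-abundance curves
#'
#' @param x a `"rank_abundance"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rank_abundance <- function(x, ...) {
  graphics::plot(x$curves$accuracy, x$curves$correct_count, type = "s",
                 xlab = "diagnostic accuracy (folded AUC)",
                 ylab = "candidate biomarkers", ...)
  graphics::lines(x$curves$accuracy, x$curves$random_count, type = "s",
                  col = "red")
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", c("correct", "random"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Select biomarker segments where the random curve declines below one
#'
#' The selection threshold `x*` is the smallest grid accuracy at which the
#' mean random count drops below 1; all segments whose folded AUC reaches
#' `x*` are selected, and the vertical distance between the curves there is
#' the excess number of candidate biomarkers beyond chance. If the random
#' curve never drops below 1 (tiny cohorts with many segments), the
#' selection is empty with a warning.
#'
#' @param curves a [rank_abundance()] result.
#' @param scores the matching [score_segments()] table.
#' @return list with `threshold` (`x*`, `NA` if none), `selected` (subset of
#'   `scores`, segment order), `excess_count`.
#' @export
select_biomarkers <- function(curves, scores) {
  stopifnot(inherits(curves, "rank_abundance"), is.data.frame(scores))
  if (curves$n_segments != nrow(scores))
    stop("curves and scores cover different segment sets")
  cv <- curves$curves
  idx <- which(cv$random_count < 1)
  if (length(idx) == 0L) {
    warning("random curve never declines below 1; no biomarkers selected")
    return(list(threshold = NA_real_,
                selected = scores[0, , drop = FALSE],
                excess_count = 0))
  }
  i <- idx[1L]
  xstar <- cv$accuracy[i]
  eps <- 1e-9
  sel <- scores[scores$folded_auc >= xstar - eps, , drop = FALSE]
  list(threshold = xstar,
       selected = sel[order(sel$segment), , drop = FALSE],
       excess_count = cv$correct_count[i] - cv$random_count[i])
}

#' Merge selected segments generated by adjacent detector scans
#'
#' A single volatile biomarker can light up several closely adjacent
#' segments of the time series; runs of selected segments separated by at
#' most `max_gap` unselected segments are merged into one biomarker peak.
#' The representative segment of a run is its highest folded AUC (tie:
#' earliest segment).
#'
#' @param selected selection table (rows of [score_segments()] output), as
#'   returned in `select_biomarkers()$selected`.
#' @param max_gap maximum inter-segment gap bridged by a merge (default 1).
#' @return data frame of merged peaks: `start_segment`, `end_segment`,
#'   `n_segments`, `representative`, `folded_auc`, `direction`.
#' @export
merge_adjacent <- function(selected, max_gap = 1L) {
  empty <- data.frame(start_segment = integer(0), end_segment = integer(0),
                      n_segments = integer(0), representative = integer(0),
                      folded_auc = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(selected) || nrow(selected) == 0L) return(empty)
  selected <- selected[order(selected$segment), , drop = FALSE]
  seg <- selected$segment
  gap <- c(0L, diff(seg) - 1L)
  run <- cumsum(gap > max_gap) + 1L
  do.call(rbind, lapply(split(seq_along(seg), run), function(ii) {
    sub <- selected[ii, , drop = FALSE]
    best <- which(sub$folded_auc == max(sub$folded_auc))[1L]  # earliest tie
    data.frame(start_segment = min(sub$segment),
               end_segment = max(sub$segment),
               n_segments = nrow(sub),
               representative = sub$segment[best],
               folded_auc = sub$folded_auc[best],
               direction = sub$direction[best],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Run the full biomarker-discovery stage on a gradient matrix
#'
#' Scores all segments, builds the permutation null, forms the
#' correct/random rank-abundance curves, applies the below-one selection
#' rule, and merges adjacent signals.
#'
#' @param gm a [gradient_matrix()].
#' @param n_reps permutation repetitions (default 40).
#' @param seed integer seed for the permutation null.
#' @param grid_step accuracy-grid spacing.
#' @param max_gap merge gap (see [merge_adjacent()]).
#' @return object of class `"discovery_result"`: `scores`, `null`, `curves`,
#'   `threshold`, `selected`, `merged`, `excess_count`.
#' @export
discover_biomarkers <- function(gm, n_reps = 40L, seed = 1L,
                                grid_step = 0.005, max_gap = 1L) {
  scores <- score_segments(gm)
  null <- permutation_null(gm, n_reps = n_reps, seed = seed)
  curves <- rank_abundance(scores, null, grid_step = grid_step)
  sel <- select_biomarkers(curves, scores)
  merged <- merge_adjacent(sel$selected, max_gap = max_gap)
  structure(
    list(scores = scores, null = null, curves = curves,
         threshold = sel$threshold, selected = sel$selected,
         merged = merged, excess_count = sel$excess_count),
    class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> %d segments; threshold %s; %d selected segments -> %d merged biomarker peak(s); excess %.2f\n",
              nrow(x$scores),
              if (is.na(x$threshold)) "none" else format(x$threshold),
              nrow(x$selected), nrow(x$merged), x$excess_count))
  invisible(x)
}
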