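round_half_up <- function(x) floor(x + 0.5)

#' Project test performance onto a screened population
#'
#' Computes the expected 2x2 outcome of screening `population` people at the
#' given disease `prevalence` with a test of the given sensitivity and
#' specificity, plus positive and negative predictive values before and
#' after the test and the corresponding enrichment factors
#' (post-test value / pre-test value, with `PPV = TP/(TP+FP)` and
#' `NPV = TN/(TN+FN)`).
#'
#' Counts are rounded half-up to whole people before the predictive values
#' are computed (the convention of published screening projections); pass
#' `exact = TRUE` to keep fractional expected counts instead. Enrichment
#' factors are computed from the full-precision predictive values, not from
#' their 3-decimal display rounding.
#'
#' @param sensitivity,specificity test performance, proportions in `[0, 1]`.
#' @param prevalence disease prevalence, proportion in `[0, 1]`.
#' @param population number of people screened.
#' @param exact if `TRUE`, skip integer rounding of the expected counts.
#' @return object of class `"screening_projection"`: `tp`, `fp`, `fn`, `tn`,
#'   `ppv_pre`, `ppv_post`, `npv_pre`, `npv_post` (percent),
#'   `enrichment_ppv`, `enrichment_npv`, `ppv_defined`, `npv_defined`, and
#'   the echoed inputs.
#' @export
project_screening <- function(sensitivity, specificity, prevalence,
                              population, exact = FALSE) {
  for (p in list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence))
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop("sensitivity, specificity and prevalence must be single proportions in [0, 1]")
  if (!is.numeric(population) || length(population) != 1L || population < 1)
    stop("population must be >= 1")
  rnd <- if (exact) identity else round_half_up
  diseased <- rnd(prevalence * population)
  healthy <- population - diseased
  tp <- rnd(sensitivity * diseased)
  fn <- diseased - tp
  tn <- rnd(specificity * healthy)
  fp <- healthy - tn
  ppv_defined <- (tp + fp) > 0
  npv_defined <- (tn + fn) > 0
  ppv_post <- if (ppv_defined) 100 * tp / (tp + fp) else NA_real_
  npv_post <- if (npv_defined) 100 * tn / (tn + fn) else NA_real_
  structure(
    list(population = population, prevalence = prevalence,
         sensitivity = sensitivity, specificity = specificity,
         tp = tp, fp = fp, fn = fn, tn = tn,
         ppv_pre = 100 * prevalence, ppv_post = ppv_post,
         npv_pre = 100 * (1 - prevalence), npv_post = npv_post,
         enrichment_ppv = if (ppv_defined && prevalence > 0)
           ppv_post / (100 * prevalence) else NA_real_,
         enrichment_npv = if (npv_defined && prevalence < 1)
           npv_post / (100 * (1 - prevalence)) else NA_real_,
         ppv_defined = ppv_defined, npv_defined = npv_defined,
         exact = exact),
    class = "screening_projection")
}

#' @export
print.screening_projection <- function(x, ...) {
  cat(sprintf("Screening %s people, prevalence %.4g%%, sensitivity %.1f%%, specificity %.1f%%\n",
              format(x$population, big.mark = ","), 100 * x$prevalence,
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("                 disease+        disease-\n"))
  cat(sprintf("  test positive  TP = %-10s FP = %s\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ",")))
  cat(sprintf("  test negative  FN = %-10s TN = %s\n",
              format(x$fn, big.mark = ","), format(x$tn, big.mark = ",")))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("  PPV pre/post: %s%% / %s%%  (enrichment %s)\n",
              fmt(x$ppv_pre), fmt(x$ppv_post), fmt(x$enrichment_ppv)))
  cat(sprintf("  NPV pre/post: %s%% / %s%%  (enrichment %s)\n",
              fmt(x$npv_pre), fmt(x$npv_post), fmt(x$enrichment_npv)))
  invisible(x)
}

#' Sweep screening projections over sensitivity/specificity grids
#'
#' @param sens_grid,spec_grid numeric vectors of proportions.
#' @param prevalence,population as in [project_screening()].
#' @param exact passed through.
#' @return data frame with one row per (sensitivity, specificity) pair and
#'   the projection fields as columns.
#' @export
screening_sweep <- function(sens_grid, spec_grid, prevalence, population,
                            exact = FALSE) {
  if (length(sens_grid) == 0L || length(spec_grid) == 0L)
    stop("grids must be non-empty")
  grid <- expand.grid(sensitivity = sens_grid, specificity = spec_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- project_screening(grid$sensitivity[i], grid$specificity[i],
                           prevalence, population, exact = exact)
    data.frame(sensitivity = p$sensitivity, specificity = p$specificity,
               tp = p$tp, fp = p$fp, fn = p$fn, tn = p$tn,
               ppv_post = p$ppv_post, npv_post = p$npv_post,
               enrichment_ppv = p$enrichment_ppv,
               enrichment_npv = p$enrichment_npv)
  })
  do.call(rbind, rows)
}
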