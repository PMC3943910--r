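#' Configuration for the synthetic breath-cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: Gaussian chromatographic peaks on a noisy flat baseline, a
#' room-air background sharing the same peak positions at a fixed fraction of
#' each subject's breath amplitudes, and a configurable subset of
#' "informative" peaks whose breath amplitude is shifted in disease subjects.
#' Amplitudes are log-normal (abundances are positive and right-skewed) and
#' the disease effect is applied on the log scale before exponentiation, so
#' large effect sizes cannot produce negative abundances.
#'
#' @param n_disease,n_control subjects per group.
#' @param n_scans scans per chromatogram (default 3013, one minute at the
#'   instrument scan rate).
#' @param n_peaks total VOC peaks per chromatogram (shared cohort chemistry).
#' @param n_informative number of peaks whose alveolar gradient differs
#'   between groups; must be `<= n_peaks`.
#' @param effect_size mean shift of informative log-amplitudes in disease, in
#'   units of the within-group (between-subject) log-SD.
#' @param peak_width_scans Gaussian sigma of each peak, in scans.
#' @param baseline_level flat baseline, detector units.
#' @param noise_sd white detector noise SD, detector units.
#' @param air_fraction fraction of each peak's breath amplitude also present
#'   in the subject's room air (subject-shared ambient amplitudes).
#' @param seed integer seed governing all randomness in the cohort.
#' @param peak_amplitude median peak height (detector units) about which
#'   cohort-level peak amplitudes are drawn.
#' @param amplitude_sdlog_between log-SD of cohort-level mean amplitudes
#'   across peaks.
#' @param amplitude_sdlog_within within-group between-subject log-SD of peak
#'   amplitudes (the SD unit in which `effect_size` is expressed).
#' @param scan_rate scans per minute stamped on generated chromatograms.
#' @return a validated object of class `"sim_config"`.
#' @export
sim_config <- function(n_disease = 40L, n_control = 40L, n_scans = 3013L,
                       n_peaks = 30L, n_informative = 5L, effect_size = 2.0,
                       peak_width_scans = 12, baseline_level = 10,
                       noise_sd = 1, air_fraction = 0.4, seed = 1L,
                       peak_amplitude = 50, amplitude_sdlog_between = 0.5,
                       amplitude_sdlog_within = 0.25, scan_rate = 3013) {
  cfg <- list(n_disease = as.integer(n_disease),
              n_control = as.integer(n_control),
              n_scans = as.integer(n_scans), n_peaks = as.integer(n_peaks),
              n_informative = as.integer(n_informative),
              effect_size = as.numeric(effect_size),
              peak_width_scans = as.numeric(peak_width_scans),
              baseline_level = as.numeric(baseline_level),
              noise_sd = as.numeric(noise_sd),
              air_fraction = as.numeric(air_fraction),
              seed = as.integer(seed),
              peak_amplitude = as.numeric(peak_amplitude),
              amplitude_sdlog_between = as.numeric(amplitude_sdlog_between),
              amplitude_sdlog_within = as.numeric(amplitude_sdlog_within),
              scan_rate = as.numeric(scan_rate))
  with(cfg, {
    if (n_disease < 1L || n_control < 1L) stop("need at least one subject per group")
    if (n_scans < 1L) stop("n_scans must be >= 1")
    if (n_peaks < 1L) stop("n_peaks must be >= 1")
    if (n_informative < 0L || n_informative > n_peaks)
      stop("n_informative must lie in [0, n_peaks]")
    if (effect_size < 0) stop("effect_size must be >= 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (air_fraction < 0 || air_fraction > 1) stop("air_fraction must be in [0, 1]")
    if (peak_width_scans <= 0) stop("peak_width_scans must be > 0")
  })
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed derivation: every per-subject (and per-fold) stream
# is a pure function of (master seed, key string); result is a valid 32-bit
# R seed regardless of key.
derive_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(as.character(key)))
    h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Add one Gaussian peak (height `amp`, centre `centre`, sigma `sig`) to a
# response vector, evaluated only on a +/- 6 sigma window for speed.
add_peak <- function(response, centre, amp, sig) {
  n <- length(response)
  lo <- max(1L, floor(centre - 6 * sig) + 1L)
  hi <- min(n, ceiling(centre + 6 * sig) + 1L)
  s <- (lo:hi) - 1L
  response[lo:hi] <- response[lo:hi] + amp * exp(-((s - centre)^2) / (2 * sig^2))
  response
}

#' Generate a synthetic cohort of paired breath/air chromatograms
#'
#' Peak centres are drawn once per cohort (all subjects share the same
#' chemistry) with a minimum mutual separation so distinct peaks remain
#' distinct after segmentation. Each subject's breath response is
#' `baseline + sum of Gaussian peaks + white noise`; the room-air response is
#' `baseline + air_fraction * (the same peaks at the subject's amplitudes) +
#' independent noise`, so subtracting air removes the shared ambient
#' background. Informative peaks get a `+/- effect_size * sdlog_within` shift
#' of their log-amplitude in disease subjects (direction fixed per peak).
#' Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with `records` (list of [subject_record()]) and `truth`
#'   (class `"sim_truth"`): peak centres, informative indices and directions,
#'   and the subjects-by-peaks amplitude matrix.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  centers <- draw_peak_centers(config$n_peaks, config$n_scans,
                               config$peak_width_scans)
  informative <- if (config$n_informative > 0L)
    sort(sample.int(config$n_peaks, config$n_informative)) else integer(0)
  direction <- if (config$n_informative > 0L)
    sample(c(-1L, 1L), config$n_informative, replace = TRUE) else integer(0)
  mu_log <- stats::rnorm(config$n_peaks, log(config$peak_amplitude),
                         config$amplitude_sdlog_between)

  n <- config$n_disease + config$n_control
  labels <- rep(c("disease", "control"), c(config$n_disease, config$n_control))
  ids <- sprintf("S%03d", seq_len(n))
  amps <- matrix(NA_real_, n, config$n_peaks,
                 dimnames = list(ids, NULL))
  shift <- numeric(config$n_peaks)
  shift[informative] <- direction * config$effect_size *
    config$amplitude_sdlog_within

  records <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, ids[i]))
    mu_i <- mu_log + if (labels[i] == "disease") shift else 0
    a <- exp(stats::rnorm(config$n_peaks, mu_i, config$amplitude_sdlog_within))
    amps[i, ] <- a
    breath <- rep(config$baseline_level, config$n_scans)
    for (j in seq_len(config$n_peaks))
      breath <- add_peak(breath, centers[j], a[j], config$peak_width_scans)
    air <- config$baseline_level +
      config$air_fraction * (breath - config$baseline_level)
    if (config$noise_sd > 0) {
      breath <- breath + stats::rnorm(config$n_scans, 0, config$noise_sd)
      air <- air + stats::rnorm(config$n_scans, 0, config$noise_sd)
    }
    records[[i]] <- subject_record(
      ids[i], labels[i],
      breath = chromatogram(breath, "breath", ids[i], config$scan_rate),
      air = chromatogram(air, "air", ids[i], config$scan_rate))
  }
  truth <- structure(
    list(peak_centers = centers,
         informative_peaks = informative,
         informative_peak_centers = centers[informative],
         informative_direction = direction,
         amplitudes = amps,
         config = config),
    class = "sim_truth")
  list(records = records, truth = truth)
}

# Peak centres uniform on the interior of the scan axis with a minimum
# separation (rejection sampling; separation relaxed if the axis is too
# crowded to honour it).
draw_peak_centers <- function(n_peaks, n_scans, sigma) {
  margin <- min(6 * sigma, n_scans / 4)
  min_sep <- 10 * sigma
  span <- n_scans - 1 - 2 * margin
  if (span <= 0) { margin <- 0; span <- n_scans - 1 }
  while (min_sep > 0 && (n_peaks - 1) * min_sep > 0.8 * span)
    min_sep <- min_sep / 2
  for (attempt in 1:200) {
    c0 <- sort(stats::runif(n_peaks, margin, margin + span))
    if (n_peaks == 1L || all(diff(c0) >= min_sep)) return(c0)
  }
  # fall back to even spacing with jitter
  base <- seq(margin, margin + span, length.out = n_peaks)
  jitter <- stats::runif(n_peaks, -min_sep / 4, min_sep / 4)
  sort(base + jitter)
}

#' Write a synthetic cohort to disk
#'
#' Emits one breath and one air chromatogram CSV per subject, a cohort
#' manifest readable by [read_cohort()], and a `truth.json` recording planted
#' peak positions for test assertions.
#'
#' @param records list of [subject_record()] (non-empty).
#' @param truth the `"sim_truth"` object from [generate_cohort()], or `NULL`.
#' @param out_dir output directory (created if needed).
#' @return path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(records, truth = NULL, out_dir) {
  if (length(records) == 0L) stop("cannot write an empty cohort")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  rows <- lapply(records, function(r) {
    bp <- paste0(r$subject_id, "_breath.csv")
    ap <- paste0(r$subject_id, "_air.csv")
    write_chromatogram(r$breath, file.path(out_dir, bp))
    write_chromatogram(r$air, file.path(out_dir, ap))
    data.frame(subject_id = r$subject_id, label = r$label,
               breath_path = bp, air_path = ap, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    tr <- truth[c("peak_centers", "informative_peaks",
                  "informative_peak_centers", "informative_direction")]
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         digits = NA, auto_unbox = FALSE)
  }
  invisible(manifest_path)
}

#' Score recovery of planted peaks by a biomarker selection
#'
#' A planted informative peak counts as recovered when some merged biomarker
#' peak covers the segment containing its centre (within `tol_segments`).
#' Merged peaks covering no planted centre are false peaks.
#'
#' @param merged merged-peak table from [merge_adjacent()].
#' @param truth a `"sim_truth"` object.
#' @param scheme the [segment_scheme()] used in the analysis.
#' @param tol_segments slack, in segments, around each merged run.
#' @return list with `n_planted`, `n_recovered`, `recovered` (logical per
#'   planted peak), `n_false` (merged peaks matching no planted centre).
#' @export
evaluate_recovery <- function(merged, truth, scheme, tol_segments = 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(scheme, "segment_scheme"))
  centers_seg <- if (length(truth$informative_peak_centers))
    scan_to_segment(truth$informative_peak_centers, scheme) else integer(0)
  if (nrow(merged) == 0L)
    return(list(n_planted = length(centers_seg), n_recovered = 0L,
                recovered = rep(FALSE, length(centers_seg)), n_false = 0L))
  hit <- vapply(centers_seg, function(s)
    any(merged$start_segment - tol_segments <= s &
        merged$end_segment + tol_segments >= s), logical(1))
  false_peak <- vapply(seq_len(nrow(merged)), function(i)
    !any(centers_seg >= merged$start_segment[i] - tol_segments &
         centers_seg <= merged$end_segment[i] + tol_segments), logical(1))
  list(n_planted = length(centers_seg), n_recovered = sum(hit),
       recovered = hit, n_false = sum(false_peak))
}
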