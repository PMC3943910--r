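#' Construct a GC-SAW chromatogram
#'
#' A chromatogram is one trace from the gas chromatograph / surface acoustic
#' wave detector: an ordered series of detector-response values, one per
#' detector scan, tagged as an exhaled-breath or an ambient room-air sample.
#' Retention time for scan `i` (0-based) is `i / scan_rate` minutes.
#'
#' @param response numeric vector of detector responses (arbitrary units),
#'   one value per scan, in elution order. Must be non-empty and finite.
#' @param sample_kind `"breath"` or `"air"`.
#' @param subject_id opaque subject identifier string.
#' @param scan_rate detector scans per minute; the instrument default is 3013.
#' @return an object of class `"chromatogram"`.
#' @seealso [read_chromatogram()], [alveolar_gradients()]
#' @export
chromatogram <- function(response, sample_kind = c("breath", "air"),
                         subject_id = "unknown", scan_rate = 3013) {
  sample_kind <- match.arg(sample_kind)
  response <- as.numeric(response)
  if (length(response) < 1L)
    stop("chromatogram response must contain at least one scan")
  if (!all(is.finite(response)))
    stop("chromatogram response contains non-finite values (first at scan ",
         which(!is.finite(response))[1L] - 1L, ")")
  if (!is.numeric(scan_rate) || length(scan_rate) != 1L || scan_rate <= 0)
    stop("scan_rate must be a single positive number")
  structure(
    list(subject_id = as.character(subject_id),
         sample_kind = sample_kind,
         scan_rate = as.numeric(scan_rate),
         response = response),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> subject %s, %s sample: %d scans (%.3f min at %g scans/min)\n",
              x$subject_id, x$sample_kind, length(x$response),
              length(x$response) / x$scan_rate, x$scan_rate))
  invisible(x)
}

#' Number of scans in a chromatogram
#' @param x a `chromatogram`.
#' @return integer scan count.
#' @export
n_scans <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  length(x$response)
}

#' Read a chromatogram from a two-column CSV file
#'
#' The file must have a header `scan,response` (0-based scan index) or
#' `time_min,response` (retention time in minutes). The first column must be
#' strictly increasing; the response column must be numeric and finite.
#'
#' @param path path to the CSV file.
#' @inheritParams chromatogram
#' @return a `chromatogram`.
#' @export
read_chromatogram <- function(path, sample_kind = c("breath", "air"),
                              subject_id = "unknown", scan_rate = 3013) {
  sample_kind <- match.arg(sample_kind)
  if (!file.exists(path)) stop("chromatogram file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || !names(df)[1L] %in% c("scan", "time_min") ||
      names(df)[2L] != "response")
    stop("expected header 'scan,response' or 'time_min,response' in ", path)
  axis <- suppressWarnings(as.numeric(df[[1L]]))
  resp <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(resp))
  if (length(bad))
    stop("non-numeric or non-finite response in ", path,
         " at data row ", bad[1L])
  if (anyNA(axis) || any(diff(axis) <= 0))
    stop("first column of ", path, " must be strictly increasing")
  chromatogram(resp, sample_kind, subject_id, scan_rate)
}

#' Write a chromatogram to CSV at full precision
#'
#' @param x a `chromatogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  lines <- c("scan,response",
             sprintf("%d,%.17g", seq_along(x$response) - 1L, x$response))
  writeLines(lines, path)
  invisible(path)
}

#' Pair a subject's breath and room-air chromatograms
#'
#' Every breath test collects a breath sample and a separate room-air sample;
#' the pair is the unit on which alveolar gradients are computed. The two
#' traces must have identical scan counts and scan rates (mismatches are an
#' error, never silently padded or truncated).
#'
#' @param subject_id subject identifier.
#' @param label group label, `"disease"` or `"control"`.
#' @param breath,air `chromatogram` objects of the matching `sample_kind`.
#' @return an object of class `"subject_record"`.
#' @export
subject_record <- function(subject_id, label = c("disease", "control"),
                           breath, air) {
  label <- match.arg(label)
  stopifnot(inherits(breath, "chromatogram"), inherits(air, "chromatogram"))
  if (breath$sample_kind != "breath" || air$sample_kind != "air")
    stop("subject_record needs a breath chromatogram and an air chromatogram")
  if (length(breath$response) != length(air$response))
    stop("breath and air chromatograms of subject ", subject_id,
         " differ in scan count (", length(breath$response), " vs ",
         length(air$response), "); refusing to pad or truncate")
  if (breath$scan_rate != air$scan_rate)
    stop("breath and air chromatograms of subject ", subject_id,
         " differ in scan_rate")
  structure(
    list(subject_id = as.character(subject_id), label = label,
         breath = breath, air = air),
    class = "subject_record")
}

#' Read a cohort of paired chromatograms from a manifest
#'
#' The manifest is a CSV with columns `subject_id,label,breath_path,air_path`;
#' file paths are resolved relative to the manifest's directory. Labels must
#' come from the two configured group names and subject ids must be unique.
#'
#' @param manifest_path path to the manifest CSV.
#' @param labels length-2 character vector naming the disease and control
#'   groups as they appear in the manifest, in that order.
#' @param scan_rate scans per minute applied to every chromatogram.
#' @return a list of [subject_record()] objects.
#' @export
read_cohort <- function(manifest_path, labels = c("disease", "control"),
                        scan_rate = 3013) {
  if (!file.exists(manifest_path))
    stop("cohort manifest not found: ", manifest_path)
  stopifnot(length(labels) == 2L)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "breath_path", "air_path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject_id in manifest: ",
         m$subject_id[duplicated(m$subject_id)][1L])
  bad <- setdiff(unique(m$label), labels)
  if (length(bad))
    stop("unknown group label '", bad[1L], "' in manifest (expected ",
         paste(labels, collapse = " or "), ")")
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(m)), function(i) {
    bp <- resolve(m$breath_path[i]); ap <- resolve(m$air_path[i])
    for (p in c(bp, ap))
      if (!file.exists(p))
        stop("manifest references missing file: ", p)
    subject_record(
      m$subject_id[i],
      label = if (m$label[i] == labels[1L]) "disease" else "control",
      breath = read_chromatogram(bp, "breath", m$subject_id[i], scan_rate),
      air    = read_chromatogram(ap, "air", m$subject_id[i], scan_rate))
  })
}

#' Tile the scan axis into contiguous segments
#'
#' Chromatograms are segmented into a time series of fixed-width windows;
#' each window later yields one alveolar gradient. Segments are half-open
#' `[start, end)` in 0-based scan coordinates, tiled left to right; the last
#' segment may be short. The width is an analysis choice (the instrument does
#' not impose one); the default of 30 scans is about 0.6 s at 3013 scans/min,
#' so a typical chromatographic peak spans one to three segments.
#'
#' @param n_scans total scans in the chromatograms to be segmented.
#' @param width_scans segment width in scans (positive integer).
#' @return an object of class `"segment_scheme"` with elements `n_scans`,
#'   `width_scans`, `n_segments`, and a matrix `bounds` of `[start, end)`.
#' @export
segment_scheme <- function(n_scans, width_scans = 30L) {
  n_scans <- as.integer(n_scans); width_scans <- as.integer(width_scans)
  if (is.na(n_scans) || n_scans < 1L) stop("n_scans must be >= 1")
  if (is.na(width_scans) || width_scans < 1L) stop("width_scans must be >= 1")
  n_seg <- as.integer(ceiling(n_scans / width_scans))
  start <- (seq_len(n_seg) - 1L) * width_scans
  end <- pmin(start + width_scans, n_scans)
  structure(
    list(n_scans = n_scans, width_scans = width_scans, n_segments = n_seg,
         bounds = cbind(start = start, end = end)),
    class = "segment_scheme")
}

#' @export
print.segment_scheme <- function(x, ...) {
  cat(sprintf("<segment_scheme> %d scans in %d segments of width %d (last %d)\n",
              x$n_scans, x$n_segments, x$width_scans,
              x$bounds[x$n_segments, "end"] - x$bounds[x$n_segments, "start"]))
  invisible(x)
}

#' Segment index containing a scan position
#'
#' @param scan 0-based scan position(s).
#' @param scheme a [segment_scheme()].
#' @return 1-based segment index/indices.
#' @export
scan_to_segment <- function(scan, scheme) {
  stopifnot(inherits(scheme, "segment_scheme"))
  idx <- floor(scan / scheme$width_scans) + 1
  if (any(scan < 0 | scan >= scheme$n_scans))
    stop("scan position outside the segmented axis")
  as.integer(idx)
}

#' Per-segment alveolar gradients for one subject
#'
#' The alveolar gradient of a segment is the aggregated detector response in
#' alveolar breath minus the aggregated response in ambient room air over the
#' same scans. Positive gradients suggest endogenous production of the
#' underlying volatile compound, negative gradients net uptake or clearance.
#' No baseline correction or peak picking is applied: the method operates on
#' raw segmented signal differences.
#'
#' @param record a [subject_record()].
#' @param scheme a [segment_scheme()] built for the record's scan count.
#' @param aggregate within-segment aggregation, `"sum"` (area-like, default)
#'   or `"mean"`.
#' @return an object of class `"gradient_profile"`: list with `subject_id`,
#'   `label`, `gradients` (numeric, one per segment), `aggregate`.
#' @export
alveolar_gradients <- function(record, scheme, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(record, "subject_record"), inherits(scheme, "segment_scheme"))
  ns <- length(record$breath$response)
  if (scheme$n_scans != ns)
    stop("segment scheme was built for ", scheme$n_scans,
         " scans but subject ", record$subject_id, " has ", ns)
  g <- segment_aggregate(record$breath$response, scheme, aggregate) -
       segment_aggregate(record$air$response, scheme, aggregate)
  structure(
    list(subject_id = record$subject_id, label = record$label,
         gradients = g, aggregate = aggregate),
    class = "gradient_profile")
}

# Aggregate a response vector within each segment of a scheme.
segment_aggregate <- function(response, scheme, aggregate) {
  seg <- rep.int(seq_len(scheme$n_segments),
                 scheme$bounds[, "end"] - scheme$bounds[, "start"])
  tot <- as.numeric(rowsum(response, seg, reorder = TRUE))
  if (aggregate == "mean")
    tot <- tot / as.numeric(scheme$bounds[, "end"] - scheme$bounds[, "start"])
  tot
}

#' n-alkane retention ladder for Kovats calibration
#'
#' The instrument is calibrated daily with an external standard, a mixture of
#' C6 to C22 n-alkanes; their retention times anchor the Kovats retention
#' index scale (C_n elutes at index 100 n).
#'
#' @param carbon_numbers integer alkane carbon numbers, strictly increasing.
#' @param retention_times matching retention times in minutes, strictly
#'   increasing.
#' @return an object of class `"alkane_ladder"`.
#' @export
alkane_ladder <- function(carbon_numbers, retention_times) {
  carbon_numbers <- as.integer(carbon_numbers)
  retention_times <- as.numeric(retention_times)
  if (length(carbon_numbers) != length(retention_times) ||
      length(carbon_numbers) < 2L)
    stop("ladder needs at least two (carbon_number, retention_time) pairs")
  if (any(diff(carbon_numbers) <= 0) || any(diff(retention_times) <= 0))
    stop("carbon numbers and retention times must be strictly increasing")
  structure(list(carbon_numbers = carbon_numbers,
                 retention_times = retention_times),
            class = "alkane_ladder")
}

#' Read an alkane ladder from CSV (`carbon_number,rt_min`)
#' @param path CSV path.
#' @return an [alkane_ladder()].
#' @export
read_alkane_ladder <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("carbon_number", "rt_min") %in% names(df)))
    stop("alkane ladder CSV must have columns carbon_number,rt_min")
  alkane_ladder(df$carbon_number, df$rt_min)
}

#' Kovats retention index of a retention time
#'
#' Isothermal-convention linear interpolation between the bracketing
#' n-alkanes: `RI = 100 * (n + (rt - rt_n) / (rt_next - rt_n) * (n_next - n))`.
#' No extrapolation: retention times outside the ladder are an error.
#'
#' @param rt_minutes retention time(s) in minutes.
#' @param ladder an [alkane_ladder()].
#' @return Kovats index, dimensionless (vectorised over `rt_minutes`).
#' @export
kovats_index <- function(rt_minutes, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  rt <- as.numeric(rt_minutes)
  lo <- min(ladder$retention_times); hi <- max(ladder$retention_times)
  if (any(rt < lo | rt > hi))
    stop("retention time outside the alkane ladder range [",
         format(lo), ", ", format(hi), "] min; no extrapolation")
  stats::approx(ladder$retention_times, 100 * ladder$carbon_numbers,
                xout = rt, method = "linear", ties = "ordered")$y
}
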