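# Per-operation concentration time series: container, I/O, blank subtraction,
# single-point calibration, totals and summaries.

#' Construct an ion/compound concentration time series
#'
#' Container for one operation's real-time VOC record: a strictly increasing
#' time axis (seconds from record start; the instrument samples at 1 Hz), one
#' concentration column per ion or compound (ppb by volume), and labelled
#' measurement segments. Segments are half-open `[start, end)` windows in
#' seconds; the conventional protocol is an instrument blank, a standard-gas
#' calibration, the operation itself, and a closing blank.
#'
#' Negative concentrations are permitted (they arise after blank
#' subtraction); all values must be finite.
#'
#' @param op_id Operation identifier.
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param conc Numeric matrix, `length(time)` rows, one named column per
#'   channel; or a data.frame coercible to such a matrix.
#' @param segments Named list of `c(start, end)` windows in seconds. Must
#'   include a non-empty `operation` window for summaries; `blank_pre` and
#'   `calib` are required by [subtract_blank()] and [calibrate()].
#' @return An object of class `ion_ts`.
#' @export
ion_series <- function(op_id, time, conc, segments) {
  conc <- as.matrix(conc)
  if (is.null(colnames(conc)) || any(!nzchar(colnames(conc)))) {
    stop("ion_series: every channel must be named")
  }
  if (length(time) != nrow(conc)) {
    stop("ion_series: time and concentration lengths differ")
  }
  if (ncol(conc) < 1) stop("ion_series: at least one channel required")
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("ion_series: time must be finite and strictly increasing")
  }
  if (any(!is.finite(conc))) stop("ion_series: concentrations must be finite")
  segments <- lapply(segments, function(w) {
    w <- as.numeric(w)
    if (length(w) != 2 || w[1] >= w[2]) {
      stop("ion_series: segment windows must be [start, end) with start < end")
    }
    w
  })
  structure(list(op_id = as.character(op_id), time = time, conc = conc,
                 segments = segments),
            class = "ion_ts")
}

#' @export
print.ion_ts <- function(x, ...) {
  cat("Ion time series '", x$op_id, "': ", length(x$time), " samples x ",
      ncol(x$conc), " channels\n", sep = "")
  cat("segments:", paste(sprintf("%s [%g,%g)", names(x$segments),
                                 vapply(x$segments, `[`, 0, 1),
                                 vapply(x$segments, `[`, 0, 2)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Channel names of an ion time series
#' @param series An `ion_ts`.
#' @return Character vector of channel names.
#' @export
channels <- function(series) colnames(series$conc)

# Logical index of samples falling in a named segment (half-open window).
segment_index <- function(series, segment) {
  w <- series$segments[[segment]]
  if (is.null(w)) {
    stop("processing error in operation '", series$op_id,
         "': segment '", segment, "' not defined")
  }
  idx <- series$time >= w[1] & series$time < w[2]
  if (!any(idx)) {
    stop("processing error in operation '", series$op_id,
         "': segment '", segment, "' contains no samples")
  }
  idx
}

#' Subtract the pre-operation instrument blank
#'
#' Per channel, subtracts the mean concentration over the `blank_pre` segment
#' from every sample, removing instrument background as measured before the
#' operation. Negative results are retained (clipping would bias means and
#' totals upward). Segment definitions are preserved.
#'
#' @param series An `ion_ts` with a non-empty `blank_pre` segment.
#' @return The blank-subtracted `ion_ts`.
#' @export
subtract_blank <- function(series) {
  idx <- segment_index(series, "blank_pre")
  blank_mean <- colMeans(series$conc[idx, , drop = FALSE])
  series$conc <- sweep(series$conc, 2, blank_mean, "-")
  series
}

#' Apply single-point calibration from the standard-gas segment
#'
#' Per channel, computes a sensitivity factor `standard_ppb / mean(calib
#' segment)` and multiplies every sample by it, so that the calibration
#' segment reads the known standard concentration. One factor per channel per
#' operation; within-operation drift is not modelled. Channels without a
#' standard are left unchanged and recorded in the `uncalibrated` attribute.
#'
#' @param series An `ion_ts` with a non-empty `calib` segment.
#' @param standard_ppb Named numeric vector of standard-gas concentrations
#'   (ppb) for the channels to calibrate; must be > 0.
#' @return Calibrated `ion_ts` with attributes `calib_factor` (named vector)
#'   and `uncalibrated` (character vector of untouched channels).
#' @export
calibrate <- function(series, standard_ppb) {
  if (is.null(names(standard_ppb)) || any(!nzchar(names(standard_ppb)))) {
    stop("calibration error: standard_ppb must be a named vector")
  }
  unknown <- setdiff(names(standard_ppb), channels(series))
  if (length(unknown) > 0) {
    stop("calibration error: unknown channel(s) ",
         paste(unknown, collapse = ", "))
  }
  if (any(standard_ppb <= 0)) {
    stop("calibration error: standard concentrations must be > 0")
  }
  idx <- segment_index(series, "calib")
  calib_mean <- colMeans(series$conc[idx, names(standard_ppb), drop = FALSE])
  if (any(calib_mean <= 0)) {
    bad <- names(standard_ppb)[calib_mean <= 0]
    stop("calibration error: non-positive calibration-segment mean for ",
         paste(bad, collapse = ", "))
  }
  factor <- standard_ppb / calib_mean
  for (ch in names(factor)) {
    series$conc[, ch] <- series$conc[, ch] * factor[[ch]]
  }
  attr(series, "calib_factor") <- factor
  attr(series, "uncalibrated") <- setdiff(channels(series), names(factor))
  series
}

#' Pointwise total concentration over a channel subset
#'
#' Sums the selected channels sample-by-sample into a single-channel series.
#' With all channels this is the "total VOC" trace; with the harmful-panel
#' compounds it is the harmful total.
#'
#' @param series An `ion_ts`.
#' @param channel_subset Character vector of channel names, or `"all"`.
#' @param name Name for the output channel.
#' @return Single-channel `ion_ts` with the same time axis and segments.
#' @export
total_voc <- function(series, channel_subset = "all", name = "total") {
  sel <- if (identical(channel_subset, "all")) {
    channels(series)
  } else {
    unknown <- setdiff(channel_subset, channels(series))
    if (length(unknown) > 0) {
      stop("lookup error: unknown channel(s) ", paste(unknown, collapse = ", "))
    }
    channel_subset
  }
  tot <- rowSums(series$conc[, sel, drop = FALSE])
  ion_series(series$op_id, series$time,
             matrix(tot, ncol = 1, dimnames = list(NULL, name)),
             series$segments)
}

#' Summarise one operation's concentration record
#'
#' Computes, over the operation segment only (blanks and calibration
#' excluded): per-channel mean and maximum concentration and the normalised
#' time of the maximum (`argmax_time_fraction` = time from segment start to
#' the first sample attaining the channel maximum, divided by segment
#' length — ties break toward the earliest sample); the total-VOC mean and
#' maximum over all channels; and, when a registry is supplied, the
#' harmful-panel total (pointwise sum over panel compounds present among the
#' channels).
#'
#' @param series An `ion_ts` with a non-empty `operation` segment.
#' @param design An [operation_design()] (carried through to the result), or
#'   `NULL`.
#' @param registry A `compound_table` defining the harmful panel, or `NULL`.
#' @return An `operation_summary`: list with `op_id`, `design`,
#'   `channel_stats` (data.frame: channel, mean_ppb, max_ppb,
#'   argmax_time_fraction), `total_voc_mean_ppb`, `total_voc_max_ppb`,
#'   `harmful_total_mean_ppb`, `harmful_total_max_ppb` (NA without registry).
#' @export
summarize_operation <- function(series, design = NULL, registry = NULL) {
  idx <- segment_index(series, "operation")
  w <- series$segments[["operation"]]
  seg_time <- series$time[idx]
  seg <- series$conc[idx, , drop = FALSE]
  seg_len <- w[2] - w[1]
  ch_mean <- colMeans(seg)
  ch_max <- apply(seg, 2, max)
  argmax_i <- apply(seg, 2, which.max)   # which.max: first (earliest) tie
  argmax_frac <- (seg_time[argmax_i] - w[1]) / seg_len
  tot <- rowSums(seg)
  harmful_mean <- NA_real_
  harmful_max <- NA_real_
  if (!is.null(registry)) {
    panel <- intersect(registry$name, channels(series))
    if (length(panel) > 0) {
      htot <- rowSums(seg[, panel, drop = FALSE])
      harmful_mean <- mean(htot)
      harmful_max <- max(htot)
    }
  }
  structure(list(
    op_id = series$op_id,
    design = design,
    channel_stats = data.frame(channel = channels(series),
                               mean_ppb = unname(ch_mean),
                               max_ppb = unname(ch_max),
                               argmax_time_fraction = unname(argmax_frac),
                               stringsAsFactors = FALSE),
    total_voc_mean_ppb = mean(tot),
    total_voc_max_ppb = max(tot),
    harmful_total_mean_ppb = harmful_mean,
    harmful_total_max_ppb = harmful_max
  ), class = "operation_summary")
}

#' @export
print.operation_summary <- function(x, ...) {
  cat("Operation summary '", x$op_id, "' (", nrow(x$channel_stats),
      " channels)\n", sep = "")
  cat(sprintf("  total VOC mean %.2f ppb, max %.2f ppb\n",
              x$total_voc_mean_ppb, x$total_voc_max_ppb))
  if (!is.na(x$harmful_total_mean_ppb)) {
    cat(sprintf("  harmful panel mean %.2f ppb, max %.2f ppb\n",
                x$harmful_total_mean_ppb, x$harmful_total_max_ppb))
  }
  invisible(x)
}

#' Flatten operation summaries to a one-row-per-operation table
#'
#' @param summaries List of `operation_summary` objects.
#' @return data.frame with op_id, design factors (when present), duration,
#'   and the four total columns.
#' @export
summaries_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    d <- s$design
    data.frame(op_id = s$op_id,
               ses = if (is.null(d)) NA_character_ else d$ses,
               approach = if (is.null(d)) NA_character_ else d$approach,
               location = if (is.null(d)) NA_character_ else d$location,
               duration_s = if (is.null(d)) NA_real_ else d$duration,
               total_voc_mean_ppb = s$total_voc_mean_ppb,
               total_voc_max_ppb = s$total_voc_max_ppb,
               harmful_total_mean_ppb = s$harmful_total_mean_ppb,
               harmful_total_max_ppb = s$harmful_total_max_ppb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read an ion time series with its metadata sidecar
#'
#' The series is a CSV with header `time_s,<channel>,...`; the sidecar is a
#' YAML file recording the operation id, segment windows (half-open, seconds)
#' and, when available, the design factors.
#'
#' @param series An `ion_ts`.
#' @param path CSV output path; the sidecar is written to `<path>.meta.yml`.
#' @param design Optional [operation_design()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_ion_series <- function(series, path, design = NULL) {
  df <- data.frame(time_s = series$time, series$conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(op_id = series$op_id,
               segments = lapply(series$segments, as.numeric))
  if (!is.null(design)) {
    meta$design <- design[c("op_id", "approach", "ses", "location", "duration")]
  }
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_ion_series
#' @param path CSV path written by [write_ion_series()].
#' @return For `read_ion_series`: the `ion_ts`, with the design (if stored)
#'   in attribute `design`.
#' @export
read_ion_series <- function(path) {
  meta_path <- paste0(path, ".meta.yml")
  if (!file.exists(meta_path)) {
    stop("processing error: metadata sidecar not found: ", meta_path)
  }
  meta <- yaml::read_yaml(meta_path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") {
    stop("processing error: first column must be time_s in ", path)
  }
  out <- ion_series(meta$op_id, df$time_s,
                    as.matrix(df[-1]), meta$segments)
  if (!is.null(meta$design)) {
    attr(out, "design") <- do.call(operation_design, meta$design)
  }
  out
}
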