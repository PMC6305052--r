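#' Quality-control and cleaning configuration
#'
#' Parameters for the four-stage FHR preprocessing pipeline:
#' (1) missing-value census with rejection when the total missing duration
#' exceeds `max_total_missing_s`; (2) rejection when any single
#' consecutive signal-loss run exceeds `max_gap_s`; (3) linear
#' interpolation of remaining gaps; (4) spike stabilization (jumps above
#' `spike_jump_bpm` bridged to the next stable point, where stability
#' means `stable_window` consecutive successive differences each below
#' `stable_diff_bpm`) followed by Savitzky-Golay smoothing.
#'
#' @param max_total_missing_s reject when total missing time strictly
#'   exceeds this many seconds (default 10).
#' @param max_gap_s reject when the longest missing run strictly exceeds
#'   this many seconds (default 30).
#' @param spike_jump_bpm successive-difference threshold flagging an
#'   unstable segment (default 25 bpm).
#' @param stable_window number of consecutive successive differences that
#'   must be small for a point to count as stable (default 5).
#' @param stable_diff_bpm the "small" threshold for those differences
#'   (default 10 bpm, strict `<`).
#' @param sg_window Savitzky-Golay window length in samples, odd and
#'   greater than `sg_order` (default 15 = 7.5 s at 2 Hz).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @return list of class `"qc_config"`.
#' @export
qc_config <- function(max_total_missing_s = 10, max_gap_s = 30,
                      spike_jump_bpm = 25, stable_window = 5,
                      stable_diff_bpm = 10, sg_window = 15, sg_order = 3) {
  cfg <- list(max_total_missing_s = max_total_missing_s,
              max_gap_s = max_gap_s,
              spike_jump_bpm = spike_jump_bpm,
              stable_window = as.integer(stable_window),
              stable_diff_bpm = stable_diff_bpm,
              sg_window = as.integer(sg_window),
              sg_order = as.integer(sg_order))
  if (cfg$sg_window %% 2L == 0L || cfg$sg_window <= cfg$sg_order) {
    stop("`sg_window` must be odd and > `sg_order`")
  }
  for (f in c("max_total_missing_s", "max_gap_s", "spike_jump_bpm",
              "stable_diff_bpm")) {
    stopifnot_scalar_number(cfg[[f]], f, positive = TRUE)
  }
  if (cfg$stable_window < 1) stop("`stable_window` must be >= 1")
  structure(cfg, class = "qc_config")
}

#' Census of missing (zero-coded) points in a record
#'
#' Counts zero-valued samples and the longest consecutive zero run,
#' converts both to seconds at the record's sampling interval, and applies
#' the rejection rules via [qc_filter()].
#'
#' @param record an `fhr_record` or bare numeric vector.
#' @param cfg a [qc_config()].
#' @param sample_interval seconds per sample; taken from the record's
#'   metadata when present.
#' @return list of class `"qc_report"` with fields
#'   `total_missing_points`, `total_missing_s`, `longest_gap_points`,
#'   `longest_gap_s`, `rejected`, `reject_reason`.
#' @export
scan_missing <- function(record, cfg = qc_config(), sample_interval = NULL) {
  values <- if (inherits(record, "fhr_record")) record$values else record
  if (length(values) < 1) stop("record must have length >= 1")
  si <- sample_interval %||%
    (if (inherits(record, "fhr_record")) record$meta$sample_interval else NULL) %||%
    0.5
  miss <- values == 0
  total <- sum(miss)
  longest <- if (total == 0) 0L else {
    r <- rle(miss)
    max(r$lengths[r$values])
  }
  rep <- structure(list(
    record_id = if (inherits(record, "fhr_record")) record$record_id else NA_character_,
    total_missing_points = as.integer(total),
    total_missing_s = total * si,
    longest_gap_points = as.integer(longest),
    longest_gap_s = longest * si,
    rejected = FALSE, reject_reason = "none"
  ), class = "qc_report")
  dec <- qc_filter(rep, cfg)
  rep$rejected <- dec$rejected
  rep$reject_reason <- dec$reason
  rep
}

#' Accept/reject decision from a QC report
#'
#' Rejects when total missing time strictly exceeds
#' `cfg$max_total_missing_s` (reason `total_missing`) or the longest gap
#' strictly exceeds `cfg$max_gap_s` (reason `long_gap`). Both comparisons
#' are strict, so a record at exactly the threshold is retained; the
#' total-missing rule is evaluated first and wins when both fire.
#'
#' @param report a `qc_report` (only the duration fields are used).
#' @param cfg a [qc_config()].
#' @return list with `rejected` (logical) and `reason` (one of `"none"`,
#'   `"total_missing"`, `"long_gap"`).
#' @export
qc_filter <- function(report, cfg = qc_config()) {
  if (report$total_missing_s > cfg$max_total_missing_s) {
    list(rejected = TRUE, reason = "total_missing")
  } else if (report$longest_gap_s > cfg$max_gap_s) {
    list(rejected = TRUE, reason = "long_gap")
  } else {
    list(rejected = FALSE, reason = "none")
  }
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report%s: %d missing points (%.1f s), longest gap %d (%.1f s) -> %s\n",
              if (is.na(x$record_id)) "" else paste0(" [", x$record_id, "]"),
              x$total_missing_points, x$total_missing_s,
              x$longest_gap_points, x$longest_gap_s,
              if (x$rejected) paste("REJECT:", x$reject_reason) else "accept"))
  invisible(x)
}

#' Repair zero-coded gaps by linear interpolation
#'
#' Interior zero runs are replaced by the straight line between the
#' nearest nonzero neighbours; leading/trailing runs are filled by
#' constant extension of the nearest valid value.
#'
#' @param values bpm sequence in which 0 codes a missing sample.
#' @return the sequence with no zeros.
#' @export
#' @examples
#' interpolate_gaps(c(140, 0, 0, 146))  # 140 142 144 146
interpolate_gaps <- function(values) {
  ok <- values != 0
  if (!any(ok)) stop("all values missing: nothing to anchor interpolation")
  if (all(ok)) return(values)
  if (sum(ok) == 1) return(rep(unname(values[ok]), length(values)))
  idx <- seq_along(values)
  stats::approx(idx[ok], values[ok], xout = idx, method = "linear",
                rule = 2)$y
}

#' Stabilize spike artifacts by bridging to the next stable point
#'
#' Scans left to right. When a successive difference exceeds
#' `cfg$spike_jump_bpm`, the following samples are treated as unstable
#' until the first index `j` from which the next `cfg$stable_window`
#' successive absolute differences are each strictly below
#' `cfg$stable_diff_bpm` (the "new stable heart rate"). Samples strictly
#' between the pre-jump point and `j` are replaced by the straight line
#' between them; if no stable point exists before the end of the trace,
#' the pre-jump value is extended to the end. The scan resumes at the
#' stable point, so isolated spikes on an otherwise stable trace are
#' removed completely while genuine gradual accelerations (successive
#' differences below the jump threshold) pass through untouched.
#'
#' @param values bpm sequence with no missing values.
#' @param cfg a [qc_config()].
#' @return the stabilized sequence.
#' @export
stabilize_spikes <- function(values, cfg = qc_config()) {
  if (any(values == 0)) stop("run interpolate_gaps() first: zeros present")
  v <- values
  n <- length(v)
  if (n < 2) return(v)
  jump <- cfg$spike_jump_bpm
  w <- cfg$stable_window
  sd_thr <- cfg$stable_diff_bpm
  i <- 1L
  while (i < n) {
    if (abs(v[i + 1L] - v[i]) > jump) {
      j <- NA_integer_
      jj <- i + 1L
      while (jj + w <= n) {
        d <- abs(v[(jj + 1L):(jj + w)] - v[jj:(jj + w - 1L)])
        if (all(d < sd_thr)) { j <- jj; break }
        jj <- jj + 1L
      }
      if (is.na(j)) {
        v[(i + 1L):n] <- v[i]
        break
      }
      if (j > i + 1L) {
        k <- j - i
        v[(i + 1L):(j - 1L)] <- v[i] + (v[j] - v[i]) * seq_len(k - 1L) / k
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  v
}

#' Savitzky-Golay smoothing of an FHR trace
#'
#' Least-squares polynomial smoothing over a centred sliding window,
#' delegated to [signal::sgolayfilt()]; boundary samples are fitted on the
#' asymmetric truncated windows, so polynomials up to `sg_order` are
#' reproduced exactly over the whole trace. This removes the single-sample
#' "jagged" measurement jitter while preserving accelerations and
#' decelerations, which last much longer than the window.
#'
#' @param values bpm sequence with no missing values, length >= `sg_window`.
#' @param cfg a [qc_config()].
#' @return smoothed sequence of the same length.
#' @export
sg_smooth <- function(values, cfg = qc_config()) {
  if (length(values) < cfg$sg_window) {
    stop("trace shorter than the smoothing window")
  }
  as.numeric(signal::sgolayfilt(values, p = cfg$sg_order, n = cfg$sg_window))
}

#' Run the full preprocessing pipeline on one record
#'
#' Applies, in order: missing-value census, the two rejection rules,
#' linear gap interpolation, spike stabilization, Savitzky-Golay
#' smoothing. Rejected records return their QC report (class
#' `"qc_rejection"`) instead of a signal.
#'
#' @param record an `fhr_record`.
#' @param cfg a [qc_config()].
#' @param sample_interval seconds per sample (default from record
#'   metadata, else 0.5).
#' @return a `clean_signal` (fields `values`, `provenance`, `source_id`)
#'   or a `qc_rejection` carrying the `qc_report`.
#' @export
run_pipeline <- function(record, cfg = qc_config(), sample_interval = NULL) {
  values <- if (inherits(record, "fhr_record")) record$values else record
  id <- if (inherits(record, "fhr_record")) record$record_id else NA_character_
  report <- scan_missing(record, cfg, sample_interval)
  if (report$rejected) {
    return(structure(list(report = report, source_id = id),
                     class = "qc_rejection"))
  }
  v <- interpolate_gaps(values)
  v <- stabilize_spikes(v, cfg)
  v <- sg_smooth(v, cfg)
  v <- pmin(pmax(v, 1e-6), 299.999)  # guard the physiological range
  structure(list(
    values = v,
    provenance = list(
      scan_missing = report[c("total_missing_points", "longest_gap_points")],
      qc = cfg[c("max_total_missing_s", "max_gap_s")],
      interpolate_gaps = list(),
      stabilize_spikes = cfg[c("spike_jump_bpm", "stable_window",
                               "stable_diff_bpm")],
      sg_smooth = cfg[c("sg_window", "sg_order")]
    ),
    source_id = id
  ), class = "clean_signal")
}

#' @export
print.clean_signal <- function(x, ...) {
  cat(sprintf("Clean FHR signal%s: %d points, range [%.1f, %.1f] bpm, %d steps applied\n",
              if (is.na(x$source_id)) "" else paste0(" [", x$source_id, "]"),
              length(x$values), min(x$values), max(x$values),
              length(x$provenance)))
  invisible(x)
}

#' @export
print.qc_rejection <- function(x, ...) {
  cat(sprintf("Rejected record %s (%s)\n", x$source_id,
              x$report$reject_reason))
  invisible(x)
}
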