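# Dataset JSON dialect and feature-table CSV.
#
# One file per dataset: {"records":[{"id": str, "fhr": [int x n], "label": 0|1}]}
# with 0 coding a missing sample. The feature CSV uses the clinical
# column names ("Baseline", "Acceleration time", ...) with a "Result"
# column coded 1 (normal) / 2 (abnormal) on disk.

FEATURE_DISK_NAMES <- c(
  baseline = "Baseline", acceleration_time = "Acceleration time",
  acceleration_magnitude = "Acceleration magnitude", frequency = "Frequency",
  period = "Period", acceleration = "Acceleration",
  acceleration_amplitude = "Acceleration amplitude",
  deceleration = "Deceleration", deceleration_period = "Deceleration period",
  result = "Result")

#' Write FHR records to dataset JSON
#'
#' @param records list of `fhr_record` or an `fhr_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_json <- function(records, path) {
  if (inherits(records, "fhr_dataset")) records <- records$records
  payload <- list(records = lapply(records, function(r) {
    list(id = r$record_id, fhr = as.integer(round(r$values)),
         label = r$label)
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read FHR records from dataset JSON
#'
#' Validates each record (keys present, expected length, values zero or
#' in (0, 300), label 0/1). Malformed records are collected into an
#' error report (attribute `"errors"`, a data frame of id and reason)
#' rather than aborting the whole read; an empty record list yields an
#' empty dataset with a warning.
#'
#' @param path dataset JSON path.
#' @param n_points expected trace length (default 2400).
#' @return list of `fhr_record` with attribute `errors`.
#' @export
read_dataset_json <- function(path, n_points = 2400) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- raw$records
  if (is.null(recs) || length(recs) == 0) {
    warning("dataset contains no records")
    return(structure(list(), errors = data.frame(id = character(),
                                                 reason = character())))
  }
  out <- list()
  errs <- list()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    id <- as.character(r$id %||% sprintf("<record %d>", i))
    reason <- NULL
    v <- suppressWarnings(as.numeric(unlist(r$fhr)))
    if (is.null(r$fhr) || is.null(r$label)) {
      reason <- "missing keys"
    } else if (any(is.na(v))) {
      reason <- "non-numeric values"
    } else if (length(v) != n_points) {
      reason <- sprintf("length %d != %d", length(v), n_points)
    } else if (any(v < 0 | v >= 300)) {
      reason <- "values outside [0, 300)"
    } else if (!r$label %in% c(0, 1)) {
      reason <- "label not in {0, 1}"
    }
    if (is.null(reason)) {
      out[[length(out) + 1L]] <- fhr_record(id, v, as.integer(r$label))
    } else {
      errs[[length(errs) + 1L]] <- data.frame(id = id, reason = reason)
    }
  }
  structure(out, errors = if (length(errs)) do.call(rbind, errs) else
    data.frame(id = character(), reason = character()))
}

#' Write the feature table as CSV with clinical column names
#'
#' @param features data frame with the in-memory (snake_case) names and a
#'   `result` column; labels 0/1 are recoded to the on-disk 1/2
#'   convention when a `label` column is supplied instead.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- features
  if (!"result" %in% names(df) && "label" %in% names(df)) {
    df$result <- df$label + 1L
    df$label <- NULL
  }
  df <- df[, names(FEATURE_DISK_NAMES)]
  names(df) <- unname(FEATURE_DISK_NAMES)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical feature CSV
#'
#' @param path CSV path with the clinical column names.
#' @return data frame with in-memory names; `result` keeps the 1/2 disk
#'   codes and a derived `label` column maps 1 to 0 and 2 to 1.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(FEATURE_DISK_NAMES), names(df))
  if (length(missing)) {
    stop("feature CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  df <- df[, unname(FEATURE_DISK_NAMES)]
  names(df) <- names(FEATURE_DISK_NAMES)
  if (!all(df$result %in% c(1, 2))) stop("Result column must be coded 1/2")
  df$label <- df$result - 1L
  df
}

#' Write per-record QC reports as CSV
#'
#' Columns: record_id, total_missing_s, longest_gap_s, rejected, reason.
#'
#' @param reports list of `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(record_id = r$record_id, total_missing_s = r$total_missing_s,
               longest_gap_s = r$longest_gap_s, rejected = r$rejected,
               reason = r$reject_reason)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
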