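#' Simulation parameters for synthetic fetal heart rate traces
#'
#' Builds the parameter set consumed by [simulate_trace()] and
#' [simulate_dataset()]. A trace is a 20-minute fetal heart rate (FHR)
#' recording sampled at 2 Hz (2400 points), the acquisition geometry of
#' bedside cardiotocography monitors. The generator emulates the artifact
#' structure of real recordings: Doppler signal loss stored as zero values,
#' and isolated spike artifacts exceeding 25 bpm.
#'
#' Two class presets are provided. Class 0 ("normal") has a baseline inside
#' the normal 110--160 bpm band, moderate short-term variability and
#' occasional accelerations. Class 1 ("abnormal") follows standard CTG
#' interpretation of non-reassuring traces: baseline outside 110--160 bpm,
#' reduced variability (< 5 bpm) and an elevated deceleration rate. These
#' presets are a modeling choice, not a clinical claim.
#'
#' @param class_index 0 (normal) or 1 (abnormal); selects the preset that
#'   unspecified arguments default to.
#' @param n_points number of samples per record (default 2400).
#' @param sample_interval seconds between samples (default 0.5 s, so the
#'   defaults span exactly 20 minutes).
#' @param baseline_bpm baseline heart rate in bpm.
#' @param variability_bpm approximate peak-to-peak band of short-term
#'   variability, bpm.
#' @param accel_rate,decel_rate expected number of acceleration /
#'   deceleration events per record (Poisson).
#' @param accel_amp,decel_amp event amplitudes in bpm (both positive;
#'   decelerations are subtracted).
#' @param event_duration_s nominal event duration in seconds.
#' @param missing_profile named weights over the signal-loss categories
#'   `none` (no missing points), `short` (about 100 points), `medium`
#'   (200--500 points) and `long` (about 1000 points). The defaults
#'   (0.33, 0.511, 0.147, 0.012) mirror the missing-data census of a large
#'   hospital CTG corpus. Must sum to 1.
#' @param spike_rate expected number of spike artifacts per record.
#' @param seed integer seed, or `NULL` to draw from the ambient RNG stream.
#' @return a list of class `"sim_params"`.
#' @export
#' @examples
#' p <- sim_params(0, seed = 1)
#' rec <- simulate_trace(p)
#' table(rec$values == 0)  # zero-coded signal loss
sim_params <- function(class_index = 0,
                       n_points = 2400,
                       sample_interval = 0.5,
                       baseline_bpm = NULL,
                       variability_bpm = NULL,
                       accel_rate = NULL,
                       decel_rate = NULL,
                       accel_amp = NULL,
                       decel_amp = NULL,
                       event_duration_s = 30,
                       missing_profile = c(none = 0.33, short = 0.511,
                                           medium = 0.147, long = 0.012),
                       spike_rate = 2,
                       seed = NULL) {
  if (!class_index %in% c(0, 1)) stop("`class_index` must be 0 or 1")
  preset <- if (class_index == 0) {
    list(baseline_bpm = 140, variability_bpm = 10, accel_rate = 3,
         decel_rate = 0.5, accel_amp = 20, decel_amp = 20)
  } else {
    list(baseline_bpm = 175, variability_bpm = 3, accel_rate = 0.5,
         decel_rate = 4, accel_amp = 15, decel_amp = 30)
  }
  p <- list(
    class_index = class_index,
    n_points = as.integer(n_points),
    sample_interval = sample_interval,
    baseline_bpm = baseline_bpm %||% preset$baseline_bpm,
    variability_bpm = variability_bpm %||% preset$variability_bpm,
    accel_rate = accel_rate %||% preset$accel_rate,
    decel_rate = decel_rate %||% preset$decel_rate,
    accel_amp = accel_amp %||% preset$accel_amp,
    decel_amp = decel_amp %||% preset$decel_amp,
    event_duration_s = event_duration_s,
    missing_profile = missing_profile,
    spike_rate = spike_rate,
    seed = seed
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_points < 1) stop("`n_points` must be >= 1")
  stopifnot_scalar_number(p$sample_interval, "sample_interval", positive = TRUE)
  if (p$event_duration_s <= 0) stop("`event_duration_s` must be > 0")
  if (p$spike_rate < 0) stop("`spike_rate` must be >= 0")
  if (p$accel_rate < 0 || p$decel_rate < 0) stop("event rates must be >= 0")
  if (p$variability_bpm < 0) stop("`variability_bpm` must be >= 0")
  w <- p$missing_profile
  if (is.null(names(w)) || !setequal(names(w), c("none", "short", "medium", "long"))) {
    stop("`missing_profile` must be named none/short/medium/long")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("`missing_profile` weights must be >= 0 and sum to 1")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("FHR simulation parameters (class %d preset)\n", x$class_index))
  cat(sprintf("  %d points @ %.2g s (%.1f min), baseline %.0f bpm, variability %.1f bpm\n",
              x$n_points, x$sample_interval,
              x$n_points * x$sample_interval / 60, x$baseline_bpm,
              x$variability_bpm))
  cat(sprintf("  accel %.2g/rec (+%.0f bpm), decel %.2g/rec (-%.0f bpm), spikes %.2g/rec\n",
              x$accel_rate, x$accel_amp, x$decel_rate, x$decel_amp,
              x$spike_rate))
  cat("  missing profile:",
      paste(sprintf("%s=%.3f", names(x$missing_profile), x$missing_profile),
            collapse = " "), "\n")
  invisible(x)
}

# Clean-signal core: baseline + band-limited variability + smooth
# raised-cosine event bumps, clamped to a physiological band and rounded
# to integer bpm (monitor output resolution). No artifacts yet.
sim_clean_trace <- function(p) {
  n <- p$n_points
  v <- rep(p$baseline_bpm, n)
  if (p$variability_bpm > 0 && n > 1) {
    noise <- rnorm(n)
    sm <- as.numeric(stats::filter(noise, rep(1 / 9, 9), circular = TRUE))
    s <- stats::sd(sm)
    if (s > 0) v <- v + sm / s * (p$variability_bpm / 4)
  }
  t_s <- (seq_len(n) - 1) * p$sample_interval
  total_s <- n * p$sample_interval
  add_events <- function(v, k, amp, sign) {
    if (k == 0) return(v)
    for (i in seq_len(k)) {
      dur <- p$event_duration_s * runif(1, 0.75, 1.5)
      start <- runif(1, 0, max(total_s - dur, 0))
      inside <- t_s >= start & t_s <= start + dur
      phase <- (t_s[inside] - start) / dur
      v[inside] <- v[inside] + sign * amp * 0.5 * (1 - cos(2 * pi * phase))
      v
    }
    v
  }
  v <- add_events(v, rpois(1, p$accel_rate), p$accel_amp, +1)
  v <- add_events(v, rpois(1, p$decel_rate), p$decel_amp, -1)
  pmax(pmin(round_half_up(v), 280), 30)
}

#' Simulate one synthetic FHR record
#'
#' Generates a zero-coded FHR trace: a clean signal (baseline +
#' band-limited variability + acceleration/deceleration bumps), then spike
#' artifacts, then zero-coded missing runs drawn from the configured
#' signal-loss mixture. Deterministic given `(params$seed, record_index)`.
#'
#' @param params a [sim_params()] object.
#' @param class_index class label recorded on the record; defaults to the
#'   preset class of `params`.
#' @param record_index integer; distinct indices give independent records
#'   under the same `params$seed`.
#' @param record_id identifier string; default derived from `record_index`.
#' @return an `fhr_record`: list with `record_id`, `values` (integer bpm,
#'   0 = missing), `label` and `meta` (provenance: spike positions, missing
#'   category and count, clean trace).
#' @export
simulate_trace <- function(params, class_index = params$class_index,
                           record_index = 1L, record_id = NULL) {
  validate_sim_params(params)
  if (!class_index %in% c(0, 1)) stop("`class_index` must be 0 or 1")
  seed <- if (is.null(params$seed)) NULL else
    (as.integer(params$seed) + 7919L * as.integer(record_index)) %% 2147483629L
  with_seed(seed, {
    clean <- sim_clean_trace(params)
    v <- inject_spikes(clean, params$spike_rate)
    spikes <- attr(v, "spike_positions")
    v <- inject_missing(as.numeric(v), params$missing_profile)
    fhr_record(
      record_id = record_id %||% sprintf("rec%05d", record_index),
      values = as.numeric(v),
      label = class_index,
      meta = list(clean = clean,
                  spike_positions = spikes,
                  missing_category = attr(v, "missing_category"),
                  missing_total = attr(v, "missing_total"),
                  baseline_bpm = params$baseline_bpm,
                  sample_interval = params$sample_interval)
    )
  })
}

#' Construct/validate an FHR record
#'
#' @param record_id identifier string.
#' @param values numeric bpm values; 0 codes a missing sample, nonzero
#'   values must lie in (0, 300).
#' @param label class index, 0 or 1.
#' @param meta free-form provenance list.
#' @return a list of class `"fhr_record"`.
#' @export
fhr_record <- function(record_id, values, label, meta = list()) {
  if (!label %in% c(0, 1)) stop("`label` must be 0 or 1")
  if (any(!is.finite(values)) || any(values < 0) || any(values >= 300)) {
    stop("`values` must be 0 (missing) or in (0, 300) bpm")
  }
  structure(list(record_id = as.character(record_id),
                 values = as.numeric(values),
                 label = as.integer(label), meta = meta),
            class = "fhr_record")
}

#' @export
print.fhr_record <- function(x, ...) {
  nz <- x$values != 0
  cat(sprintf("FHR record %s: %d points, label %d, %d missing; range [%g, %g] bpm\n",
              x$record_id, length(x$values), x$label, sum(!nz),
              if (any(nz)) min(x$values[nz]) else NA,
              if (any(nz)) max(x$values[nz]) else NA))
  invisible(x)
}

#' Inject zero-coded missing runs into a trace
#'
#' Draws a signal-loss category from `profile` and zeroes that many points,
#' split into 1--3 non-overlapping runs placed uniformly at random. Total
#' zeroed points per category: `none` 0, `short` 50--150, `medium`
#' 200--500, `long` 800--1200. Positions not zeroed keep their input
#' values, and at least one point is always left intact.
#'
#' @param values bpm sequence with no zeros.
#' @param profile named weights over none/short/medium/long, summing to 1.
#' @param category optional fixed category (bypasses the draw).
#' @return the sequence with zero runs; attributes `missing_category`,
#'   `missing_total`, `missing_positions`.
#' @export
inject_missing <- function(values, profile, category = NULL) {
  if (any(values == 0)) stop("`values` must have no zeros on entry")
  if (any(profile < 0) || abs(sum(profile) - 1) > 1e-8) {
    stop("`profile` weights must be >= 0 and sum to 1")
  }
  cats <- c("none", "short", "medium", "long")
  if (is.null(names(profile)) || !setequal(names(profile), cats)) {
    stop("`profile` must be named none/short/medium/long")
  }
  cat_drawn <- category %||% sample(cats, 1, prob = profile[cats])
  n <- length(values)
  total <- switch(cat_drawn,
                  none = 0L,
                  short = sample(50:150, 1),
                  medium = sample(200:500, 1),
                  long = sample(800:1200, 1))
  total <- min(total, n - 1L)  # keep at least one anchor point
  out <- values
  pos <- integer(0)
  if (total > 0) {
    k <- sample(seq_len(min(3L, total)), 1)
    lens <- if (k == 1) total else {
      cuts <- sort(sample(seq_len(total - 1L), k - 1L))
      diff(c(0L, cuts, total))
    }
    free <- n - total
    offs <- sort(sample(0:free, k, replace = TRUE))
    starts <- offs + c(0L, cumsum(lens[-k])) + 1L
    pos <- unlist(mapply(function(s, l) seq.int(s, s + l - 1L), starts, lens,
                         SIMPLIFY = FALSE))
    out[pos] <- 0
  }
  attr(out, "missing_category") <- cat_drawn
  attr(out, "missing_total") <- length(pos)
  attr(out, "missing_positions") <- pos
  out
}

#' Inject isolated spike artifacts
#'
#' Displaces isolated points by an integer offset of magnitude 26--40 bpm
#' (always exceeding the 25 bpm jump the preprocessing stabilizer detects),
#' with the sign chosen so values stay inside (0, 300).
#'
#' @param values bpm sequence (nonzero at the chosen positions).
#' @param spike_rate expected spike count (Poisson).
#' @return the sequence with attribute `spike_positions`.
#' @export
inject_spikes <- function(values, spike_rate) {
  if (spike_rate < 0) stop("`spike_rate` must be >= 0")
  n <- length(values)
  k <- rpois(1, spike_rate)
  out <- values
  pos <- integer(0)
  if (k > 0 && n >= 3) {
    # isolated: keep at least one untouched sample between spikes
    cand <- sample(2:(n - 1), min(k * 3L, n - 2L))
    for (p in cand) {
      if (length(pos) >= k) break
      if (any(abs(pos - p) <= 1)) next
      off <- sample(26:40, 1)
      sgn <- if (out[p] + off > 290) -1 else if (out[p] - off < 10) 1 else
        sample(c(-1, 1), 1)
      out[p] <- out[p] + sgn * off
      pos <- c(pos, p)
    }
  }
  attr(out, "spike_positions") <- sort(pos)
  out
}

#' Derive a clinical-style feature vector from a clean trace
#'
#' Computes the fields of the feature table used by the SVM / random-forest
#' baselines. The baseline is the 25%-trimmed mean; accelerations
#' (decelerations) are excursions of at least +15 bpm (-15 bpm) from
#' baseline sustained for at least 15 s, the conventional CTG criterion.
#'
#' Fields: `baseline` (bpm), `acceleration` (episode count),
#' `acceleration_time` (mean episode duration, s), `acceleration_magnitude`
#' (mean episode peak excursion, bpm), `acceleration_amplitude` (largest
#' episode peak excursion, bpm), `deceleration` (episode count),
#' `deceleration_period` (mean deceleration duration, s), `frequency`
#' (baseline up-crossings per minute, a variability surrogate) and `period`
#' (mean seconds between up-crossings).
#'
#' @param values clean bpm sequence with no missing values (or a
#'   `clean_signal` object).
#' @param sample_interval seconds per sample.
#' @return one-row data frame with the nine numeric feature fields.
#' @export
derive_feature_vector <- function(values, sample_interval = 0.5) {
  if (inherits(values, "clean_signal")) values <- values$values
  if (any(values == 0)) stop("`values` must contain no missing (zero) points")
  sustain <- ceiling(15 / sample_interval)
  if (length(values) < sustain) {
    stop("trace shorter than the 15 s sustain window")
  }
  baseline <- mean(values, trim = 0.25)
  exc <- values - baseline

  episodes <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= sustain
    cbind(start = starts[keep], end = ends[keep])
  }
  acc <- episodes(exc >= 15)
  dec <- episodes(exc <= -15)
  ep_stats <- function(ep, sign) {
    if (nrow(ep) == 0) return(list(n = 0, mean_dur = 0, mean_peak = 0, max_peak = 0))
    durs <- (ep[, "end"] - ep[, "start"] + 1L) * sample_interval
    peaks <- apply(ep, 1, function(e) max(sign * exc[e[1]:e[2]]))
    list(n = nrow(ep), mean_dur = mean(durs),
         mean_peak = mean(peaks), max_peak = max(peaks))
  }
  a <- ep_stats(acc, +1)
  d <- ep_stats(dec, -1)

  up <- which(diff(exc > 0) == 1L)  # upward baseline crossings
  minutes <- length(values) * sample_interval / 60
  freq <- length(up) / minutes
  per <- if (length(up) >= 2) mean(diff(up)) * sample_interval else 0

  data.frame(baseline = baseline,
             acceleration_time = a$mean_dur,
             acceleration_magnitude = a$mean_peak,
             frequency = freq,
             period = per,
             acceleration = a$n,
             acceleration_amplitude = a$max_peak,
             deceleration = d$n,
             deceleration_period = d$mean_dur)
}

#' Simulate a labeled FHR dataset with feature table
#'
#' Generates `n` records (`round(n * class_balance)` of class 1, the rest
#' class 0), each with per-record parameter jitter: normal records draw
#' their baseline from 125--150 bpm and variability from 6--15 bpm;
#' abnormal records draw a bradycardic (95--107 bpm) or tachycardic
#' (163--180 bpm) baseline and variability 1--4.5 bpm. The feature table is
#' derived from each record's latent clean trace (emulating expert
#' annotation of the true curve) and carries a `result` column coded 1
#' (label 0) / 2 (label 1), the on-disk convention.
#'
#' @param n number of records (>= 1).
#' @param class_balance fraction of class-1 (abnormal) records, in (0, 1).
#' @param params0,params1 per-class [sim_params()].
#' @param seed integer seed; the dataset is reproducible from it.
#' @param jitter logical; disable to use the class parameters verbatim.
#' @return list of class `"fhr_dataset"`: `records` (list of
#'   `fhr_record`), `features` (data frame, one row per record, with
#'   `result`), `labels` (integer vector).
#' @export
#' @examples
#' ds <- simulate_dataset(10, seed = 1)
#' table(ds$labels)
simulate_dataset <- function(n, class_balance = 0.5,
                             params0 = sim_params(0),
                             params1 = sim_params(1),
                             seed = 1, jitter = TRUE) {
  if (n < 1) stop("`n` must be >= 1")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("`class_balance` must be in (0, 1)")
  }
  n1 <- round(n * class_balance)
  n0 <- n - n1
  if (n0 == 0 || n1 == 0) stop("degenerate class: one class has 0 samples")
  labels <- c(rep(0L, n0), rep(1L, n1))
  records <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- labels[i]
    p <- if (cls == 0) params0 else params1
    seed_i <- (as.integer(seed) + 7919L * i) %% 2147483629L
    rec <- with_seed(seed_i, {
      pj <- p
      if (jitter) {
        if (cls == 0) {
          pj$baseline_bpm <- runif(1, 125, 150)
          pj$variability_bpm <- runif(1, 6, 15)
        } else {
          pj$baseline_bpm <- if (runif(1) < 0.5) runif(1, 95, 107) else
            runif(1, 163, 180)
          pj$variability_bpm <- runif(1, 1, 4.5)
        }
      }
      pj$seed <- NULL  # draws come from the stream seeded above
      simulate_trace(pj, class_index = cls, record_index = i)
    })
    records[[i]] <- rec
    feats[[i]] <- derive_feature_vector(rec$meta$clean, p$sample_interval)
  }
  features <- do.call(rbind, feats)
  features$result <- labels + 1L
  rownames(features) <- vapply(records, `[[`, "", "record_id")
  structure(list(records = records, features = features, labels = labels),
            class = "fhr_dataset")
}

#' @export
print.fhr_dataset <- function(x, ...) {
  cat(sprintf("FHR dataset: %d records (%d normal / %d abnormal), %d feature fields\n",
              length(x$records), sum(x$labels == 0), sum(x$labels == 1),
              ncol(x$features) - 1L))
  invisible(x)
}
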