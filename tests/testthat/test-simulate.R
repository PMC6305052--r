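test_that("degenerate noiseless parameters give a constant trace", {
  p <- sim_params(0, baseline_bpm = 140, variability_bpm = 0,
                  accel_rate = 0, decel_rate = 0, spike_rate = 0,
                  missing_profile = c(none = 1, short = 0, medium = 0,
                                      long = 0),
                  seed = 1)
  rec <- simulate_trace(p)
  expect_length(rec$values, 2400)
  expect_true(all(rec$values == 140))
})

test_that("trace generation is deterministic given seed and record index", {
  p <- sim_params(0, seed = 1)
  r1 <- simulate_trace(p, record_index = 3)
  r2 <- simulate_trace(p, record_index = 3)
  expect_identical(r1$values, r2$values)
  r3 <- simulate_trace(p, record_index = 4)
  expect_false(identical(r1$values, r3$values))
})

test_that("generated records are well-formed and the defaults span 20 min", {
  p <- sim_params(1, seed = 5)
  expect_equal(p$n_points * p$sample_interval, 20 * 60)
  rec <- simulate_trace(p)
  v <- rec$values
  expect_true(all(v == 0 | (v > 0 & v < 300)))
  expect_equal(rec$label, 1L)
})

test_that("sim_params validates its invariants", {
  expect_error(sim_params(2), "class_index")
  expect_error(sim_params(0, n_points = 0), "n_points")
  expect_error(sim_params(0, sample_interval = 0), "sample_interval")
  expect_error(sim_params(0, event_duration_s = -1), "event_duration")
  expect_error(sim_params(0, missing_profile = c(none = 0.5, short = 0.5,
                                                 medium = 0.2, long = 0)),
               "sum to 1")
})

test_that("inject_missing respects the drawn category and conserves values", {
  set.seed(1)
  v <- rep(140, 2400)
  expect_identical(inject_missing(v, c(none = 1, short = 0, medium = 0,
                                       long = 0)),
                   v, ignore_attr = TRUE)
  for (i in 1:20) {
    out <- inject_missing(v, c(none = 0, short = 0, medium = 1, long = 0))
    nz <- sum(out == 0)
    expect_gte(nz, 200)
    expect_lte(nz, 500)
    # conservation: untouched positions keep their values
    expect_true(all(out[out != 0] == v[out != 0]))
    expect_equal(sum(out == 0), length(v) - sum(out != 0))
  }
  expect_error(inject_missing(v, c(none = 0.5, short = 0.1, medium = 0.1,
                                   long = 0.1)), "sum to 1")
  expect_error(inject_missing(c(0, 140), c(none = 1, short = 0, medium = 0,
                                           long = 0)), "no zeros")
})

test_that("run-length ranges match the configured categories", {
  set.seed(2)
  v <- rep(140, 2400)
  for (spec in list(c("short", 50, 150), c("medium", 200, 500),
                    c("long", 800, 1200))) {
    pr <- setNames(as.numeric(c("none", "short", "medium", "long") == spec[1]),
                   c("none", "short", "medium", "long"))
    for (i in 1:10) {
      out <- inject_missing(v, pr)
      expect_gte(sum(out == 0), as.numeric(spec[2]))
      expect_lte(sum(out == 0), as.numeric(spec[3]))
    }
  }
})

test_that("injected spikes exceed the 25 bpm detection threshold and round-trip", {
  set.seed(3)
  v <- rep(140, 200)
  expect_identical(inject_spikes(v, 0), v, ignore_attr = TRUE)
  out <- inject_spikes(v, 3)
  pos <- attr(out, "spike_positions")
  if (length(pos) > 0) {
    expect_true(all(abs(out[pos] - v[pos]) > 25))
    # all spikes isolated
    expect_true(all(diff(pos) > 1))
    # round trip through the stabilizer restores the flat trace
    fixed <- stabilize_spikes(out, qc_config())
    expect_equal(fixed, v, tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(inject_spikes(v, -1), "spike_rate")
})

test_that("feature derivation matches closed forms on rectangular pulses", {
  flat <- rep(140, 2400)
  f <- derive_feature_vector(flat)
  expect_equal(f$baseline, 140)
  expect_equal(f$acceleration, 0)
  expect_equal(f$deceleration, 0)

  bump <- flat
  bump[1001:1120] <- 160  # +20 bpm for 60 s
  f2 <- derive_feature_vector(bump)
  expect_equal(f2$baseline, 140)
  expect_equal(f2$acceleration, 1)
  expect_equal(f2$acceleration_amplitude, 20)
  expect_equal(f2$acceleration_time, 60)

  # sub-threshold bump (+10 bpm) leaves the count unchanged
  sub <- bump
  sub[2001:2120] <- 150
  f3 <- derive_feature_vector(sub)
  expect_equal(f3$acceleration, 1)

  dip <- flat
  dip[501:580] <- 120  # -20 bpm for 40 s
  f4 <- derive_feature_vector(dip)
  expect_equal(f4$deceleration, 1)
  expect_equal(f4$deceleration_period, 40)

  expect_error(derive_feature_vector(rep(140, 10)), "sustain")
})

test_that("simulate_dataset balances classes and reproduces from seed", {
  ds <- simulate_dataset(10, class_balance = 0.5, seed = 9)
  expect_equal(sum(ds$labels == 0), 5)
  expect_equal(sum(ds$labels == 1), 5)
  expect_equal(nrow(ds$features), 10)
  expect_equal(ds$features$result, ds$labels + 1L)
  expect_true(all(is.finite(as.matrix(ds$features))))
  expect_true(all(as.matrix(ds$features) >= 0))

  ds2 <- simulate_dataset(10, class_balance = 0.5, seed = 9)
  expect_identical(lapply(ds$records, `[[`, "values"),
                   lapply(ds2$records, `[[`, "values"))
  expect_error(simulate_dataset(10, class_balance = 0.01), "degenerate")
})

test_that("byte-identical JSON from the same dataset seed", {
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_dataset_json(simulate_dataset(5, seed = 4), f1)
  write_dataset_json(simulate_dataset(5, seed = 4), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("widening the class parameter gap does not hurt a threshold classifier", {
  # monotone separability on the baseline feature, small grid
  acc_for_gap <- function(gap, seed = 11) {
    p0 <- sim_params(0, baseline_bpm = 140, seed = NULL)
    p1 <- sim_params(1, baseline_bpm = 140 + gap, seed = NULL)
    ds <- simulate_dataset(60, 0.5, p0, p1, seed = seed, jitter = FALSE)
    b <- ds$features$baseline
    thr <- 140 + gap / 2
    mean((b > thr) == (ds$labels == 1))
  }
  accs <- vapply(c(5, 15, 30), acc_for_gap, 1.0)
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], 0.95)
})
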