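test_that("missing-value census counts points, runs and seconds", {
  cfg <- qc_config()
  r <- scan_missing(rep(140, 100), cfg)
  expect_equal(r$total_missing_points, 0L)
  expect_false(r$rejected)

  v <- rep(140, 2400)
  v[11:70] <- 0  # 60 points = 30 s at 2 Hz
  r2 <- scan_missing(v, cfg)
  expect_equal(r2$total_missing_s, 30)
  expect_equal(r2$longest_gap_s, 30)
  # the 30 s gap passes the strict long-gap rule, but the 30 s total
  # exceeds the 10 s total-missing budget, which is checked first
  expect_true(r2$rejected)
  expect_equal(r2$reject_reason, "total_missing")

  v3 <- rep(140, 100)
  v3[c(3, 20, 40, 60, 80)] <- 0
  r3 <- scan_missing(v3, cfg)
  expect_equal(r3$total_missing_points, 5L)
  expect_equal(r3$longest_gap_points, 1L)
})

test_that("rejection rules are strict and ordered", {
  cfg <- qc_config()
  mk <- function(total_s, gap_s) {
    list(total_missing_s = total_s, longest_gap_s = gap_s)
  }
  expect_false(qc_filter(mk(9, 5), cfg)$rejected)
  expect_false(qc_filter(mk(10, 5), cfg)$rejected)   # boundary: exactly 10 s
  d <- qc_filter(mk(10.5, 5), cfg)
  expect_true(d$rejected)
  expect_equal(d$reason, "total_missing")
  d2 <- qc_filter(mk(5, 30.5), cfg)
  expect_true(d2$rejected)
  expect_equal(d2$reason, "long_gap")
  # both fire: total-missing rule wins
  d3 <- qc_filter(mk(40, 31), cfg)
  expect_equal(d3$reason, "total_missing")
})

test_that("gap interpolation matches closed forms", {
  expect_equal(interpolate_gaps(c(140, 0, 0, 146)), c(140, 142, 144, 146))
  expect_equal(interpolate_gaps(c(0, 0, 150, 150)), c(150, 150, 150, 150))
  v <- c(120, 130, 150)
  expect_identical(interpolate_gaps(v), v)
  expect_error(interpolate_gaps(c(0, 0, 0)), "anchor")
})

test_that("interpolation matches the brute-force oracle exhaustively (short traces)", {
  alphabet <- c(0, 100, 140, 180)
  for (len in 2:6) {
    tr <- enumerate_traces(len, alphabet)
    for (i in seq_len(nrow(tr))) {
      v <- tr[i, ]
      if (all(v == 0)) next
      expect_equal(interpolate_gaps(v), oracle_interpolate(v))
    }
  }
})

test_that("interpolation matches the oracle on random longer traces", {
  set.seed(42)
  for (rep in 1:500) {
    len <- sample(7:12, 1)
    v <- sample(c(0, 100, 140, 180), len, replace = TRUE)
    if (all(v == 0)) next
    expect_equal(interpolate_gaps(v), oracle_interpolate(v))
  }
})

test_that("an isolated spike on a flat trace is removed completely", {
  v <- rep(140, 10)
  v[5] <- 190
  expect_equal(stabilize_spikes(v, qc_config()), rep(140, 10))
  # a gradual 20-bpm ramp (sub-threshold diffs) is untouched
  ramp <- c(rep(140, 10), seq(140, 160, by = 5), rep(160, 10))
  expect_identical(stabilize_spikes(ramp, qc_config()), ramp)
})

test_that("spike stabilization matches the brute-force oracle exhaustively", {
  alphabet <- c(100, 140, 180)
  for (len in 2:8) {
    tr <- enumerate_traces(len, alphabet)
    for (i in seq_len(nrow(tr))) {
      v <- tr[i, ]
      expect_equal(stabilize_spikes(v, qc_config()), oracle_stabilize(v))
    }
  }
})

test_that("spike stabilization matches the oracle on random longer traces", {
  set.seed(7)
  for (rep in 1:500) {
    len <- sample(9:12, 1)
    v <- sample(c(100, 140, 180), len, replace = TRUE)
    expect_equal(stabilize_spikes(v, qc_config()), oracle_stabilize(v))
  }
})

test_that("stabilizing twice equals stabilizing once", {
  set.seed(8)
  for (rep in 1:50) {
    v <- sample(c(100, 120, 140, 180), 30, replace = TRUE)
    s1 <- stabilize_spikes(v, qc_config())
    expect_equal(stabilize_spikes(s1, qc_config()), s1)
  }
})

test_that("Savitzky-Golay smoothing reproduces cubics and damps jitter", {
  cfg <- qc_config()
  x <- 0:199
  cubic <- 140 + 0.1 * x - 0.002 * x^2 + 1e-5 * x^3
  expect_equal(sg_smooth(cubic, cfg), cubic, tolerance = 1e-8)
  expect_equal(sg_smooth(rep(140, 50), cfg), rep(140, 50), tolerance = 1e-10)
  set.seed(9)
  jitter <- rep(140, 100)
  jitter[seq(5, 95, by = 7)] <- jitter[seq(5, 95, by = 7)] +
    sample(c(-1, 1), 13, replace = TRUE)
  sm <- sg_smooth(jitter, cfg)
  expect_lt(max(abs(sm - 140)), max(abs(jitter - 140)))
  expect_error(sg_smooth(rep(140, 5), cfg), "shorter")
  expect_error(qc_config(sg_window = 14), "odd")
  expect_error(qc_config(sg_window = 3, sg_order = 3), "odd")
})

test_that("the full pipeline composes the stages in order", {
  cfg <- qc_config()
  # clean flat record passes through within smoothing tolerance
  rec <- fhr_record("flat", rep(140, 2400), 0)
  out <- run_pipeline(rec, cfg)
  expect_s3_class(out, "clean_signal")
  expect_equal(out$values, rep(140, 2400), tolerance = 1e-8)
  expect_named(out$provenance,
               c("scan_missing", "qc", "interpolate_gaps",
                 "stabilize_spikes", "sg_smooth"))

  # 61 consecutive zeros = 30.5 s -> rejected for the long gap...
  v <- rep(140, 2400)
  v[101:161] <- 0
  rej <- run_pipeline(fhr_record("gap", v, 0), qc_config(max_total_missing_s = 60))
  expect_s3_class(rej, "qc_rejection")
  expect_equal(rej$report$reject_reason, "long_gap")

  # ...while a 9 s-total-missing record is retained and repaired
  v2 <- rep(140, 2400)
  v2[201:218] <- 0  # 18 points = 9 s
  ok <- run_pipeline(fhr_record("ok", v2, 0), cfg)
  expect_s3_class(ok, "clean_signal")
  expect_true(all(ok$values != 0))
  expect_length(ok$values, 2400)
})

test_that("gap plus spike record comes out clean with bounded jumps", {
  set.seed(10)
  v <- rep(140, 2400) + round(rnorm(2400))
  v[301] <- 180          # spike
  v[1001:1010] <- 0      # 5 s gap
  out <- run_pipeline(fhr_record("mix", v, 0), qc_config())
  expect_s3_class(out, "clean_signal")
  expect_true(all(out$values != 0))
  expect_lte(max(abs(diff(out$values))), 25)
})

test_that("pipeline is idempotent on cleaned signals up to smoothing tolerance", {
  p <- sim_params(0, missing_profile = c(none = 1, short = 0, medium = 0,
                                         long = 0),
                  spike_rate = 0, seed = 12)
  rec <- simulate_trace(p)
  once <- run_pipeline(rec, qc_config())
  again <- run_pipeline(fhr_record("x", pmax(once$values, 1), 0), qc_config())
  expect_lt(max(abs(again$values - once$values)), 2)
})
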