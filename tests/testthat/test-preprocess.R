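test_that("detrending removes drift and preserves the pulse band", {
  fs <- 100
  t <- (0:5999) / fs
  # DC is far below the cutoff
  const <- rep(80, length(t))
  out <- detrend_abp(const, fs)
  expect_lt(max(abs(out)), 1e-6 * 80)
  # 0.1 Hz drift attenuated, consistent with the response oracle
  drift <- sin(2 * pi * 0.1 * t)
  expect_lt(sd(detrend_abp(drift, fs)) / sd(drift), 0.05)
  expect_lt(detrend_gain(0.1, fs), 0.05)
  # 2 Hz pulse-band content preserved
  pulse <- sin(2 * pi * 2 * t)
  expect_lt(abs(sd(detrend_abp(pulse, fs)) / sd(pulse) - 1), 0.05)
  expect_gt(detrend_gain(2, fs), 0.95)
  expect_error(detrend_abp(c(1, 2, 3), fs), "short")
})

test_that("clean-segment selection accepts clean records and rejects
           flatlines and short records", {
  r <- clean_record()  # 60 s
  rep1 <- select_clean(r$samples, 100, min_len = 30)
  expect_equal(nrow(rep1$clean_intervals), 1)
  span <- rep1$clean_intervals$end[1] - rep1$clean_intervals$start[1] + 1
  expect_gte(span / length(r$samples), 0.95)

  # insert a 10 s flatline mid-record
  x <- r$samples
  flat_lo <- 2501; flat_hi <- 3500
  x[flat_lo:flat_hi] <- x[flat_lo]
  rep2 <- select_clean(x, 100, min_len = 10)
  expect_gt(nrow(rep2$clean_intervals), 0)
  for (i in seq_len(nrow(rep2$clean_intervals))) {
    a <- rep2$clean_intervals$start[i]; b <- rep2$clean_intervals$end[i]
    # accepted intervals never cover the flatline interior
    expect_true(b < flat_lo + 200 || a > flat_hi - 200)
  }

  rep3 <- select_clean(r$samples, 100, min_len = 600)
  expect_equal(nrow(rep3$clean_intervals), 0)
  expect_equal(rep3$rejected_fraction, 1)
})

test_that("rule-based detection recovers truth landmarks on clean input", {
  r <- clean_record()
  det <- detrend_abp(r$samples, 100)
  seg <- detect_pulses_rule(det, 100)
  expect_segmentation_valid(seg)
  err <- vapply(seg$peaks, function(p) min(abs(r$truth_peaks - p)),
                numeric(1))
  expect_gte(mean(err <= 2), 0.99)
  onset_err <- vapply(seg$onsets, function(o) min(abs(r$truth_onsets - o)),
                      numeric(1))
  expect_lte(mean(onset_err), 2)
})

test_that("pulse onset is the minimum of the 30-sample pre-peak window", {
  r <- clean_record()
  det <- detrend_abp(r$samples, 100)
  seg <- detect_pulses_rule(det, 100, smooth_sec = 0)
  p <- seg$peaks[5]
  # plant a distinctly lower sample at p - 7, inside the pre-peak window
  det2 <- det
  det2[p - 7] <- min(det[(p - 30):(p - 1)]) - 5
  seg2 <- detect_pulses_rule(det2, 100, smooth_sec = 0)
  j <- which.min(abs(seg2$peaks - p))
  # exhaustive window scan oracle
  win <- (seg2$peaks[j] - 30):(seg2$peaks[j] - 1)
  expect_equal(seg2$onsets[j], win[which.min(det2[win])])
  expect_equal(seg2$onsets[j], p - 7)
})

test_that("degenerate signals yield empty segmentations", {
  expect_length(detect_pulses_rule(seq(0, 10, length.out = 500), 100)$peaks,
                0)
  expect_length(detect_pulses_alt(rep(1, 500), 100)$peaks, 0)
})

test_that("slope-threshold detector agrees with the rule on clean input
           and tolerates noise", {
  r <- clean_record()
  det <- detrend_abp(r$samples, 100)
  seg_r <- detect_pulses_rule(det, 100)
  seg_a <- detect_pulses_alt(det, 100)
  expect_segmentation_valid(seg_a)
  expect_equal(length(seg_a$peaks), length(seg_r$peaks))

  rn <- synth_record(group_params(noise_sd = 3), 60, 100, 0, 8)
  dn <- detrend_abp(rn$samples, 100)
  sa <- detect_pulses_alt(dn, 100)
  matched <- vapply(rn$truth_peaks, function(p) min(abs(sa$peaks - p)),
                    numeric(1))
  expect_gte(mean(matched <= 3), 0.95)
})

test_that("reconciliation keeps matched beats and drops unmatched ones", {
  r <- clean_record()
  det <- detrend_abp(r$samples, 100)
  seg <- detect_pulses_rule(det, 100)
  # idempotence on identical inputs
  rec0 <- reconcile(seg, seg)
  expect_equal(rec0$peaks, seg$peaks)
  expect_equal(attr(rec0, "dropped_rule"), 0)

  # a 2-sample shift is within the 0.05 s tolerance at 100 Hz
  shifted <- seg
  shifted$peaks <- seg$peaks + 2L
  shifted$onsets <- seg$onsets + 2L
  shifted$offsets <- seg$offsets + 2L
  rec1 <- reconcile(seg, shifted)
  expect_equal(rec1$peaks, seg$peaks)
  expect_equal(attr(rec1, "dropped_rule"), 0)
  expect_equal(rec1$method_tag, "reconciled")

  # deleting one beat from the alternative drops exactly that beat
  missing <- seg
  drop_i <- 5L
  for (f in c("onsets", "peaks", "offsets"))
    missing[[f]] <- missing[[f]][-drop_i]
  rec2 <- reconcile(seg, missing)
  expect_equal(length(rec2$peaks), length(seg$peaks) - 1)
  expect_equal(attr(rec2, "dropped_rule"), 1)
  expect_false(seg$peaks[drop_i] %in% rec2$peaks)
})

test_that("instances are 300-point min-max scaled groups of k pulses", {
  r <- clean_record()
  det <- detrend_abp(r$samples, 100)
  seg <- detect_pulses_rule(det, 100)
  inst <- make_instances(det, seg, k = 3)
  expect_gt(length(inst), 0)
  for (x in inst[1:3]) {
    expect_length(x$values, 300)
    expect_equal(min(x$values), 0)
    expect_equal(max(x$values), 1)
    expect_equal(x$pulses_per_instance, 3)
  }
  # counting rule: 10 pulses, k = 3, stride 3 -> 3 instances
  seg10 <- seg
  for (f in c("onsets", "peaks", "offsets"))
    seg10[[f]] <- seg10[[f]][1:10]
  i10 <- make_instances(det, seg10, k = 3, stride = 3)
  expect_length(i10, 3)
  expect_equal(i10[[1]]$source_pulse_indices, 1:3)
  expect_equal(i10[[2]]$source_pulse_indices, 4:6)
  expect_equal(i10[[3]]$source_pulse_indices, 7:9)
  # instance-count identity across stride choices
  for (stride in 1:3) {
    got <- length(make_instances(det, seg, k = 3, stride = stride))
    expect_equal(got, floor((length(seg$peaks) - 3) / stride) + 1)
  }
  # fewer than k pulses
  seg2 <- seg
  for (f in c("onsets", "peaks", "offsets")) seg2[[f]] <- seg2[[f]][1:2]
  expect_length(make_instances(det, seg2, k = 3), 0)
})

test_that("a constant raw segment yields a flagged all-zero instance", {
  x <- rep(5, 400)
  seg <- structure(list(onsets = c(1L, 101L, 201L),
                        peaks = c(50L, 150L, 250L),
                        offsets = c(100L, 200L, 300L),
                        method_tag = "rule", fs = 100),
                   class = "segmentation_result")
  inst <- make_instances(x, seg, k = 3)
  expect_length(inst, 1)
  expect_true(inst[[1]]$degenerate)
  expect_true(all(inst[[1]]$values == 0))
})

test_that("linear resampling preserves landmark ordering", {
  r <- clean_record()
  from_len <- diff(r$truth_onsets[c(1, 4)]) + 1
  marks <- sort(c(r$truth_peaks[1:3], r$truth_notches[1:3]) -
                  r$truth_onsets[1] + 1)
  mapped <- resample_map_index(marks, from_len, 300)
  expect_true(all(diff(mapped) >= 0))
  expect_true(all(mapped >= 1 & mapped <= 300))
})

test_that("zero-noise segmentation round-trip holds across seeds", {
  errs <- c()
  for (s in 1:5) {
    r <- synth_record(group_params(noise_sd = 0, drift_amp = 0), 30, 100,
                      0, 400 + s)
    det <- detrend_abp(r$samples, 100)
    seg <- reconcile(detect_pulses_rule(det, 100),
                     detect_pulses_alt(det, 100))
    expect_segmentation_valid(seg)
    errs <- c(errs, vapply(seg$onsets, function(o)
      min(abs(r$truth_onsets - o)), numeric(1)))
  }
  expect_lte(mean(errs), 2)
})
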