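lm_manual <- function(peak, dn, dp, offset)
  structure(list(peak = peak, dn = dn, dp = dp, offset = offset,
                 dn_method = "local_min", failed = FALSE),
            class = "landmark_set")

test_that("peak-to-offset normalization maps the segment to [0, 1] and
           may push pre-peak samples outside", {
  pulse <- c(4, 6, seq(10, 2, length.out = 20))
  out <- normalize_pulse(pulse, peak_idx = 3)
  expect_equal(out[3], 1)
  expect_equal(out[length(out)], 0)
  # idempotence
  again <- normalize_pulse(as.numeric(out), 3)
  expect_equal(as.numeric(again), as.numeric(out))
  # onset below the segment minimum lands below 0
  pulse2 <- c(1, 6, seq(10, 2, length.out = 20))
  out2 <- normalize_pulse(pulse2, 3)
  expect_lt(out2[1], 0)
  # zero-range guard
  flat <- normalize_pulse(rep(3, 10), 2)
  expect_true(attr(flat, "degenerate"))
})

test_that("landmark detection finds the true notch and falls back on
           monotone decays", {
  r <- clean_record()
  fs <- 100
  det <- detrend_abp(r$samples, fs)
  seg <- reconcile(detect_pulses_rule(det, fs), detect_pulses_alt(det, fs))
  errs <- c()
  for (i in seq_len(min(30, length(seg$peaks)))) {
    on <- seg$onsets[i]
    pulse <- r$samples[on:seg$offsets[i]]
    lm <- detect_landmarks(pulse, fs, peak = seg$peaks[i] - on + 1L)
    if (lm$failed) next
    expect_equal(lm$dn_method, "local_min")
    errs <- c(errs, min(abs(r$truth_notches - (lm$dn + on - 1))))
  }
  expect_lte(median(errs), 2)

  # pure exponential decay: curvature fallback with dn == dp
  decay <- 10 * exp(-(0:60) / 20)
  lm2 <- detect_landmarks(decay, 100, peak = 1)
  expect_false(lm2$failed)
  expect_equal(lm2$dn_method, "second_derivative_fallback")
  expect_equal(lm2$dn, lm2$dp)

  # linear decay has no curvature extremum: failure flag
  lm3 <- detect_landmarks(seq(10, 0, length.out = 50), 100, peak = 1)
  expect_true(lm3$failed)
})

test_that("landmark ordering invariant holds over random synthetic
           beats", {
  set.seed(31)
  for (rep in 1:300) {
    sh <- pulse_shape(runoff_tau = runif(1, 0.5, 1.3),
                      dicrotic_amp = runif(1, 4, 14),
                      systolic_amp = runif(1, 30, 50))
    b <- synth_beat(sh, runif(1, 0.6, 1.0), 100)
    lm <- detect_landmarks(as.numeric(b), 100, peak = attr(b, "peak"))
    if (lm$failed) next
    expect_true(lm$peak < lm$dn && lm$dn <= lm$dp &&
                  lm$dp < lm$offset)
  }
})

test_that("the battery has exactly 63 fixed keys", {
  keys <- feature_keys()
  expect_length(keys, 63)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(grepl("^(P2N|N2D|D2O)_d[012]_", keys)))
})

test_that("segment statistics obey the calculus of simple series", {
  fs <- 100
  # linear series a*t: d1 constant a, d2 zero
  a <- 3.5
  t <- (0:40) / fs
  lin <- a * t
  lm <- lm_manual(peak = 1, dn = 15, dp = 25, offset = 41)
  fv <- segment_features(lin, lm, fs)
  for (seg in c("P2N", "N2D", "D2O")) {
    expect_equal(fv[[paste0(seg, "_d1_mean")]], a, tolerance = 1e-9)
    expect_equal(fv[[paste0(seg, "_d1_min")]], a, tolerance = 1e-9)
    expect_equal(fv[[paste0(seg, "_d1_max")]], a, tolerance = 1e-9)
    expect_equal(fv[[paste0(seg, "_d2_mean")]], 0, tolerance = 1e-9)
  }
  # constant unit segment: order-0 area equals duration
  const <- rep(1, 41)
  fv2 <- segment_features(const, lm, fs)
  expect_equal(fv2[["P2N_d0_area"]], (15 - 1) / fs)
  expect_equal(fv2[["D2O_d0_length"]], (41 - 25) / fs)
  # segment shorter than 3 samples is flagged NA
  lm_short <- lm_manual(1, 2, 25, 41)
  fv3 <- segment_features(lin, lm_short, fs)
  expect_true(is.na(fv3[["P2N_d1_mean"]]))
})

test_that("finite differences are exact for polynomials up to degree 2", {
  fs <- 50
  t <- (0:99) / fs
  y <- 2 - 3 * t + 0.7 * t^2
  d1 <- finite_derivative(y, fs)
  expect_equal(d1, -3 + 1.4 * t, tolerance = 1e-8)
  d2 <- finite_derivative(d1, fs)
  expect_equal(d2, rep(1.4, 100), tolerance = 1e-8)
})

test_that("halving runoff tau makes the diastolic slope strictly more
           negative, beat by beat", {
  set.seed(32)
  fs <- 100
  for (rep in 1:100) {
    tau <- runif(1, 0.8, 1.2)
    per <- runif(1, 0.7, 0.9)
    b1 <- synth_beat(pulse_shape(runoff_tau = tau), per, fs)
    b2 <- synth_beat(pulse_shape(runoff_tau = tau / 2), per, fs)
    lm1 <- detect_landmarks(as.numeric(b1), fs, peak = attr(b1, "peak"))
    lm2 <- detect_landmarks(as.numeric(b2), fs, peak = attr(b2, "peak"))
    f1 <- segment_features(as.numeric(b1), lm1, fs)[["D2O_d1_mean"]]
    f2 <- segment_features(as.numeric(b2), lm2, fs)[["D2O_d1_mean"]]
    expect_lt(f2, f1)
  }
})

test_that("IQR filtering follows the linear-interpolation quartile
           convention", {
  f <- iqr_filter(c(1, 2, 3, 100))
  expect_equal(f$removed, 1)
  expect_equal(f$values, c(1, 2, 3))
  # hand arithmetic: Q1 = 1.75, Q3 = 27.25, upper = 65.5
  expect_equal(f$bounds[2], 27.25 + 1.5 * 25.5)

  same <- iqr_filter(rep(7, 10))
  expect_equal(same$removed, 0)

  # Monte-Carlo: the 1.5 IQR rule removes ~0.7% of a Gaussian sample
  set.seed(33)
  fracs <- replicate(30, iqr_filter(rnorm(1000))$removed / 1000)
  expect_lt(abs(mean(fracs) - 0.007), 0.007)

  # idempotence on a sample whose bounds stabilize
  x <- c(1:20, 100)
  once <- iqr_filter(x)
  expect_equal(once$removed, 1)
  twice <- iqr_filter(once$values)
  expect_equal(twice$removed, 0)
})

test_that("group comparison gates the test on normality and handles
           identical groups", {
  set.seed(34)
  a <- rnorm(60); b <- rnorm(60)
  ts <- abpwave:::gated_test(a, b)
  expect_equal(ts$test, "t_test")
  skewed <- exp(rnorm(60))
  ts2 <- abpwave:::gated_test(skewed, exp(rnorm(60)))
  expect_equal(ts2$test, "u_test")
  same <- abpwave:::gated_test(c(a, 99), c(a, 99))
  expect_gt(same$p, 0.9)
})

test_that("the U-test detects a one-SD shift at n = 50 per group", {
  set.seed(35)
  hits <- 0
  for (rep in 1:100) {
    a <- rnorm(50); b <- rnorm(50) + 1
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 90)
})

test_that("point-by-point comparison controls the null and localizes a
           post-notch difference", {
  set.seed(36)
  n_pat <- 16; n_pulse <- 4; len <- 300
  base <- sin(seq(0, pi, length.out = len))
  build <- function(shift_after = NA) {
    rows <- list(); pid <- c(); lab <- c()
    for (i in 1:n_pat) {
      l <- as.integer(i <= n_pat / 2)
      for (j in 1:n_pulse) {
        v <- base + rnorm(len, 0, 0.2) + rnorm(1, 0, 0.1)
        if (!is.na(shift_after) && l == 1)
          v[shift_after:len] <- v[shift_after:len] - 1.0
        rows[[length(rows) + 1]] <- v
        pid <- c(pid, sprintf("P%d", i)); lab <- c(lab, l)
      }
    }
    list(p = do.call(rbind, rows), pid = pid, lab = lab)
  }
  null <- build()
  res0 <- pointwise_compare(null$p, null$pid, null$lab)
  # binomial bound on 300 tests at alpha 0.05
  expect_lte(length(res0$significant), qbinom(0.999, 300, 0.05))

  alt <- build(shift_after = 180)
  res1 <- pointwise_compare(alt$p, alt$pid, alt$lab)
  expect_gt(length(res1$significant), 0)
  expect_gte(mean(res1$significant >= 180), 0.8)

  expect_error(pointwise_compare(null$p[1:2, ], null$pid[1:2],
                                 c(0, 1)), "2 patients")
})

test_that("cohort feature tables carry finite filtered features and the
           significant-feature directions are reproducible", {
  recs <- synth_cohort(preset_cohort("default", n_patients = 16,
                                     event_prevalence = 0.5,
                                     duration = 20, seed = 13))
  ft <- cohort_feature_table(recs)
  expect_true(all(c("patient_id", "label", feature_keys()) %in%
                    names(ft)))
  expect_gt(nrow(ft), 100)
  res <- compare_groups(ft)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the strongest named discriminators point the same way: higher in the
  # steeper-runoff (event) group after per-pulse normalization
  expect_equal(res$direction[res$feature == "P2N_d1_mean"], 1)
  expect_equal(res$direction[res$feature == "D2O_d1_min"], 1)
})
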