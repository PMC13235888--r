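# Preprocessing: detrending, clean-segment selection, rule-based and
# slope-threshold pulse segmentation with reconciliation, and construction
# of normalized k-pulse instances.

#' Detrending configuration
#'
#' @param cutoff High-pass cutoff frequency (Hz); drift below this is
#'   removed while pulse-band components (>= 1 Hz) pass.
#' @param filter_order Butterworth filter order.
#' @param zero_phase Apply the filter forward-backward (zero phase lag).
#' @return A `detrend_config` list.
#' @export
detrend_config <- function(cutoff = 0.5, filter_order = 2,
                           zero_phase = TRUE) {
  stopifnot(cutoff > 0, filter_order >= 1)
  structure(list(cutoff = cutoff, filter_order = as.integer(filter_order),
                 zero_phase = zero_phase),
            class = "detrend_config")
}

#' Remove low-frequency drift from an ABP signal
#'
#' Zero-phase Butterworth high-pass (default 0.5 Hz, 2nd order, applied
#' forward-backward), attenuating baseline drift while preserving the
#' pulse band.
#'
#' @param x Pressure series (mmHg).
#' @param fs Sampling rate (Hz).
#' @param cfg A [detrend_config()].
#' @return Detrended series, same length as `x`.
#' @export
detrend_abp <- function(x, fs, cfg = detrend_config()) {
  stopifnot(inherits(cfg, "detrend_config"), cfg$cutoff < fs / 2)
  if (length(x) <= 3 * max(cfg$filter_order, 10))
    stop("signal too short to detrend")
  bf <- signal::butter(cfg$filter_order, cfg$cutoff / (fs / 2),
                       type = "high")
  mu <- mean(x)
  xc <- x - mu
  # reflection padding suppresses filtfilt edge transients
  n <- length(xc)
  pad <- min(n - 1, round(2 * fs / cfg$cutoff))
  xp <- c(2 * xc[1] - xc[(pad + 1):2], xc,
          2 * xc[n] - xc[(n - 1):(n - pad)])
  y <- if (cfg$zero_phase) as.numeric(signal::filtfilt(bf, xp))
       else as.numeric(signal::filter(bf, xp))
  y[(pad + 1):(pad + n)]
}

#' Theoretical amplitude response of the detrending filter
#'
#' Magnitude response at the requested frequencies; squared when
#' `zero_phase` is set, matching the forward-backward application.
#' Used as an independent oracle for attenuation checks.
#'
#' @param freqs Frequencies (Hz).
#' @param fs Sampling rate (Hz).
#' @param cfg A [detrend_config()].
#' @return Numeric gain at each frequency.
#' @export
detrend_gain <- function(freqs, fs, cfg = detrend_config()) {
  bf <- signal::butter(cfg$filter_order, cfg$cutoff / (fs / 2),
                       type = "high")
  w <- 2 * pi * freqs / fs
  ev <- function(coefs) vapply(w, function(wi)
    sum(coefs * exp(-1i * wi * (seq_along(coefs) - 1))), complex(1))
  g <- Mod(ev(bf$b) / ev(bf$a))
  if (cfg$zero_phase) g^2 else g
}

# centered moving average; k forced odd so the filter is zero-lag
smooth_ma <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1L
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y <- as.numeric(y)
  half <- k %/% 2
  y[seq_len(half)] <- y[half + 1L]
  n <- length(x)
  y[(n - half + 1L):n] <- y[n - half]
  y
}

# rolling max over centered windows (width samples), edge-padded
roll_max <- function(x, width) {
  n <- length(x)
  k <- max(1L, as.integer(width))
  half <- k %/% 2
  # block-decomposition running max (van Herk style, O(n))
  xp <- c(rep(x[1], half), x, rep(x[n], k - half - 1))
  m <- length(xp)
  nblk <- ceiling(m / k)
  pad <- nblk * k - m
  xpp <- c(xp, rep(xp[m], pad))
  mat <- matrix(xpp, nrow = k)
  fwd <- apply(mat, 2, cummax)
  bwd <- apply(mat[k:1, , drop = FALSE], 2, cummax)[k:1, , drop = FALSE]
  fwd <- as.numeric(fwd); bwd <- as.numeric(bwd)
  i <- seq_len(n)
  pmax(bwd[i], fwd[i + k - 1L])
}

roll_range <- function(x, width) {
  roll_max(x, width) + roll_max(-x, width)
}

#' Select clean intervals of an ABP record
#'
#' Automated surrogate for expert visual inspection: an interval is
#' accepted when it contains no flatline (amplitude range below
#' `flat_range` mmHg over any `flat_win`-second window), stays within
#' physiologic amplitude bounds, has a detected beat rate within
#' `rate_bounds` (beats/min), and is at least `min_len` seconds long.
#'
#' @param x Raw pressure series (mmHg).
#' @param fs Sampling rate (Hz).
#' @param min_len Minimum accepted interval length (seconds; default 600,
#'   i.e. 10 minutes).
#' @param amp_bounds Physiologic absolute pressure bounds (mmHg).
#' @param rate_bounds Acceptable beat rate (beats/min).
#' @param flat_range,flat_win Flatline definition: range < `flat_range`
#'   mmHg over `flat_win` seconds.
#' @return A `quality_report` list: `clean_intervals` (data frame of
#'   accepted `start`,`end` sample ranges), `rejected_fraction` (fraction
#'   of samples outside accepted intervals), and `reasons` (per candidate
#'   interval).
#' @export
select_clean <- function(x, fs, min_len = 600, amp_bounds = c(20, 250),
                         rate_bounds = c(40, 220), flat_range = 1,
                         flat_win = 2) {
  stopifnot(fs > 0)
  n <- length(x)
  bad <- !is.finite(x) | x < amp_bounds[1] | x > amp_bounds[2]
  if (n > flat_win * fs) {
    rr <- roll_range(x, round(flat_win * fs))
    bad <- bad | rr < flat_range
  }
  r <- rle(!bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- data.frame(start = starts[r$values], end = ends[r$values])
  reasons <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    len_s <- (cand$end[i] - cand$start[i] + 1) / fs
    if (len_s < min_len) { reasons[i] <- "too_short"; next }
    seg <- x[cand$start[i]:cand$end[i]]
    det <- detrend_abp(seg, fs)
    pk <- detect_pulses_rule(det, fs)
    rate <- 60 * length(pk$peaks) / len_s
    if (rate < rate_bounds[1] || rate > rate_bounds[2]) {
      reasons[i] <- "rate_out_of_bounds"; next
    }
    reasons[i] <- "accepted"; keep[i] <- TRUE
  }
  accepted <- cand[keep, , drop = FALSE]
  covered <- if (nrow(accepted)) sum(accepted$end - accepted$start + 1) else 0
  structure(list(
    clean_intervals = accepted,
    rejected_fraction = 1 - covered / n,
    reasons = reasons
  ), class = "quality_report")
}

new_segmentation <- function(onsets, peaks, offsets, method_tag, fs) {
  ok <- onsets < peaks & peaks < offsets
  structure(list(onsets = onsets[ok], peaks = peaks[ok],
                 offsets = offsets[ok], method_tag = method_tag, fs = fs),
            class = "segmentation_result")
}

#' Rule-based pulse segmentation
#'
#' Systolic peaks are local maxima subject to a minimum peak distance and
#' a prominence floor (rise from the preceding trough must exceed
#' `prom_frac` of the local rolling amplitude range). The pulse onset is
#' the minimum value within the `onset_win` samples preceding each peak
#' and the offset is the subsequent trough before the next peak.
#'
#' @param x Detrended pressure series.
#' @param fs Sampling rate (Hz).
#' @param min_dist Minimum distance between peaks (seconds).
#' @param prom_frac Required prominence as a fraction of the rolling
#'   (2-second) amplitude range.
#' @param onset_win Pre-peak search window for the onset, in samples
#'   (default 30, tied to 100 Hz sampling).
#' @param smooth_sec Width of the centered moving average applied before
#'   detection (seconds; 0 disables). Indices refer to the smoothed
#'   signal, which is zero-lag.
#' @return A `segmentation_result` with parallel `onsets`, `peaks`,
#'   `offsets` index vectors, `method_tag = "rule"`.
#' @export
detect_pulses_rule <- function(x, fs, min_dist = 0.3, prom_frac = 0.2,
                               onset_win = 30L, smooth_sec = 0.05) {
  n <- length(x)
  if (n < 3) return(new_segmentation(integer(0), integer(0), integer(0),
                                     "rule", fs))
  if (smooth_sec > 0) x <- smooth_ma(x, round(smooth_sec * fs))
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] > x[i + 1]]
  if (!length(cand)) return(new_segmentation(integer(0), integer(0),
                                             integer(0), "rule", fs))
  rr <- roll_range(x, round(2 * fs))
  rise <- vapply(cand, function(p) {
    lo <- max(1L, p - onset_win)
    x[p] - min(x[lo:p])
  }, numeric(1))
  cand <- cand[rise >= prom_frac * rr[cand]]
  if (!length(cand)) return(new_segmentation(integer(0), integer(0),
                                             integer(0), "rule", fs))
  # greedy minimum-distance enforcement, tallest peaks first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n + 1L)
  taken <- integer(0)
  md <- round(min_dist * fs)
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= md)) taken <- c(taken, p)
  }
  peaks <- sort(taken)
  onsets <- vapply(peaks, function(p) {
    lo <- max(1L, p - onset_win)
    win <- lo:max(lo, p - 1L)
    win[which.min(x[win])]
  }, integer(1))
  ibi <- if (length(peaks) > 1) stats::median(diff(peaks)) else round(fs)
  offsets <- vapply(seq_along(peaks), function(j) {
    p <- peaks[j]
    hi <- if (j < length(peaks)) peaks[j + 1L] - 1L
          else min(n, p + round(1.2 * ibi))
    if (hi <= p + 1L) return(NA_integer_)
    win <- (p + 1L):hi
    win[which.min(x[win])]
  }, integer(1))
  ok <- !is.na(offsets)
  new_segmentation(onsets[ok], peaks[ok], offsets[ok], "rule", fs)
}

#' Slope-threshold pulse segmentation
#'
#' Independent detector: locates systolic upstrokes where the first
#' difference exceeds an adaptive threshold (a fraction of the rolling
#' maximum slope), then anchors the onset at the preceding trough, the
#' peak at the following local maximum, and the offset at the trough
#' before the next upstroke.
#'
#' @param x Detrended pressure series.
#' @param fs Sampling rate (Hz).
#' @param thr_frac Threshold as a fraction of the rolling (2-second)
#'   maximum positive slope.
#' @param refractory Minimum separation between upstrokes (seconds).
#' @param smooth_sec Moving-average width applied before slope
#'   computation (seconds; 0 disables).
#' @return A `segmentation_result` with `method_tag = "alt"`.
#' @export
detect_pulses_alt <- function(x, fs, thr_frac = 0.4, refractory = 0.3,
                              smooth_sec = 0.05) {
  n <- length(x)
  if (n < 5) return(new_segmentation(integer(0), integer(0), integer(0),
                                     "alt", fs))
  if (smooth_sec > 0) x <- smooth_ma(x, round(smooth_sec * fs))
  d <- c(diff(x), 0)
  dmax <- roll_max(pmax(d, 0), round(2 * fs))
  if (max(dmax) <= 0) return(new_segmentation(integer(0), integer(0),
                                              integer(0), "alt", fs))
  above <- d > thr_frac * pmax(dmax, 1e-12) & d > 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  up_start <- starts[r$values]
  up_end <- ends[r$values]
  if (!length(up_start)) return(new_segmentation(integer(0), integer(0),
                                                 integer(0), "alt", fs))
  # merge upstroke runs closer than the refractory period
  ref <- round(refractory * fs)
  grp <- cumsum(c(1L, as.integer(diff(up_start) > ref)))
  up_start <- tapply(up_start, grp, min)
  up_end <- tapply(up_end, grp, max)
  back <- round(0.3 * fs); fwd <- round(0.3 * fs)
  peaks <- integer(0); onsets <- integer(0)
  for (g in seq_along(up_start)) {
    s <- up_start[g]; e <- up_end[g]
    lo <- max(1L, s - back)
    onset <- (lo:s)[which.min(x[lo:s])]
    hi <- min(n, e + fwd)
    peak <- (e:hi)[which.max(x[e:hi])]
    if (peak > onset) { onsets <- c(onsets, onset); peaks <- c(peaks, peak) }
  }
  ibi <- if (length(peaks) > 1) stats::median(diff(peaks)) else round(fs)
  offsets <- vapply(seq_along(peaks), function(j) {
    p <- peaks[j]
    hi <- if (j < length(peaks)) peaks[j + 1L] - 1L
          else min(n, p + round(1.2 * ibi))
    if (hi <= p + 1L) return(NA_integer_)
    win <- (p + 1L):hi
    win[which.min(x[win])]
  }, integer(1))
  ok <- !is.na(offsets)
  new_segmentation(as.integer(onsets[ok]), as.integer(peaks[ok]),
                   as.integer(offsets[ok]), "alt", fs)
}

#' Reconcile two segmentations of the same signal
#'
#' Beats are matched across methods by peak proximity within `tol`
#' seconds; matched beats keep the rule-based indices, unmatched beats
#' from either method are dropped and counted.
#'
#' @param rule,alt `segmentation_result`s from [detect_pulses_rule()] and
#'   [detect_pulses_alt()] on the same signal.
#' @param tol Matching tolerance (seconds; default 0.05, i.e. 5 samples
#'   at 100 Hz).
#' @return A `segmentation_result` with `method_tag = "reconciled"` and
#'   attributes `dropped_rule` / `dropped_alt` (unmatched beat counts).
#' @export
reconcile <- function(rule, alt, tol = 0.05) {
  stopifnot(inherits(rule, "segmentation_result"),
            inherits(alt, "segmentation_result"),
            rule$fs == alt$fs)
  tol_s <- tol * rule$fs
  i <- 1L; j <- 1L
  keep <- integer(0); matched_alt <- 0L
  while (i <= length(rule$peaks) && j <= length(alt$peaks)) {
    dpk <- rule$peaks[i] - alt$peaks[j]
    if (abs(dpk) <= tol_s) {
      keep <- c(keep, i); matched_alt <- matched_alt + 1L
      i <- i + 1L; j <- j + 1L
    } else if (dpk < 0) i <- i + 1L else j <- j + 1L
  }
  out <- new_segmentation(rule$onsets[keep], rule$peaks[keep],
                          rule$offsets[keep], "reconciled", rule$fs)
  attr(out, "dropped_rule") <- length(rule$peaks) - length(keep)
  attr(out, "dropped_alt") <- length(alt$peaks) - matched_alt
  out
}

#' Linear resampling to a fixed length
#'
#' @param v Numeric vector.
#' @param n Target length.
#' @return Vector of length `n` obtained by linear interpolation on a
#'   uniform grid.
#' @export
resample_linear <- function(v, n) {
  if (length(v) == n) return(v)
  stats::approx(seq_along(v), v, n = n)$y
}

#' Map a sample index through the linear resampling transform
#'
#' Gives the position in the resampled grid corresponding to index `i`
#' of a vector of length `from_len`.
#'
#' @param i Source index (1-based).
#' @param from_len Source length.
#' @param to_len Target length.
#' @return Resampled-grid index (1-based, rounded).
#' @export
resample_map_index <- function(i, from_len, to_len) {
  round((i - 1) * (to_len - 1) / (from_len - 1)) + 1
}

#' Build normalized k-pulse instances
#'
#' Groups `k` consecutive pulses (onset of the first to offset of the
#' last), linearly resamples the segment to `target_len` points and
#' min-max scales it to [0, 1] (defaults: 3 pulses, 300 points,
#' non-overlapping stride). Scaling is applied after resampling so every
#' stored instance attains 0 and 1 exactly.
#'
#' @param x Detrended pressure series.
#' @param seg A `segmentation_result` over `x`.
#' @param k Pulses per instance.
#' @param target_len Output length in samples.
#' @param stride Step between instance starts, in pulses.
#' @param patient_id,label Metadata attached to each instance.
#' @return List of `normalized_instance`s, each with fields `values`
#'   (length `target_len`, min 0 / max 1 unless degenerate),
#'   `pulses_per_instance`, `source_pulse_indices`, `patient_id`,
#'   `label`, `degenerate`.
#' @export
make_instances <- function(x, seg, k = 3, target_len = 300, stride = k,
                           patient_id = NA_character_, label = NA_integer_) {
  stopifnot(inherits(seg, "segmentation_result"), k >= 1, stride >= 1)
  np <- length(seg$peaks)
  if (np < k) return(list())
  m <- floor((np - k) / stride) + 1
  lapply(seq_len(m), function(j) {
    a <- (j - 1) * stride + 1
    b <- a + k - 1
    raw <- resample_linear(x[seg$onsets[a]:seg$offsets[b]], target_len)
    rng <- max(raw) - min(raw)
    degenerate <- rng < 1e-12
    vals <- if (degenerate) rep(0, length(raw)) else (raw - min(raw)) / rng
    structure(list(
      values = vals,
      pulses_per_instance = k,
      source_pulse_indices = a:b,
      patient_id = patient_id, label = label,
      degenerate = degenerate
    ), class = "normalized_instance")
  })
}

#' Full preprocessing of one record
#'
#' Detrend, segment with both detectors, reconcile, and build normalized
#' instances carrying the record's patient id and label.
#'
#' @param record A `waveform_record`.
#' @param k,target_len,stride Passed to [make_instances()].
#' @param cfg A [detrend_config()].
#' @return List with `instances`, `segmentation`, and the detrended
#'   signal `detrended`.
#' @export
record_instances <- function(record, k = 3, target_len = 300, stride = k,
                             cfg = detrend_config()) {
  det <- detrend_abp(record$samples, record$sampling_rate, cfg)
  seg_r <- detect_pulses_rule(det, record$sampling_rate)
  seg_a <- detect_pulses_alt(det, record$sampling_rate)
  seg <- reconcile(seg_r, seg_a)
  inst <- make_instances(det, seg, k = k, target_len = target_len,
                         stride = stride, patient_id = record$patient_id,
                         label = record$label)
  list(instances = inst, segmentation = seg, detrended = det)
}
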