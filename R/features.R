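# Notch-centered pulse features: landmark detection (dicrotic notch,
# diastolic peak), per-pulse normalization from systolic peak to offset,
# the 63-feature battery (3 segments x derivative orders 0/1/2 x 7
# statistics), IQR outlier filtering, and normality-gated two-group
# comparison plus a point-by-point comparison of aligned pulses.

SEGMENTS <- c("P2N", "N2D", "D2O")
STATS <- c("length", "slope", "min", "max", "mean", "median", "area")

.feature_keys <- local({
  g <- expand.grid(stat = c("length", "slope", "min", "max", "mean",
                            "median", "area"),
                   d = 0:2, seg = c("P2N", "N2D", "D2O"),
                   stringsAsFactors = FALSE)
  sprintf("%s_d%d_%s", g$seg, g$d, g$stat)
})

#' The fixed feature key set
#'
#' @return Character vector of the 63 feature names, formatted
#'   `segment_dORDER_statistic` (e.g. `P2N_d1_mean`).
#' @export
feature_keys <- function() .feature_keys

#' Normalize a pulse from systolic peak to offset
#'
#' Min-max scaling whose range is computed over the peak-to-offset
#' segment only but applied to the whole pulse, so the peak maps to 1
#' and the segment minimum to 0; pre-peak samples may fall outside
#' [0, 1].
#'
#' @param pulse Pressure series of one pulse (onset to offset).
#' @param peak_idx Systolic peak index within the pulse.
#' @param offset_idx Offset index (default: last sample).
#' @return Normalized series with attribute `degenerate` set when the
#'   segment range is zero.
#' @export
normalize_pulse <- function(pulse, peak_idx, offset_idx = length(pulse)) {
  stopifnot(peak_idx >= 1, peak_idx < offset_idx,
            offset_idx <= length(pulse))
  seg <- pulse[peak_idx:offset_idx]
  rng <- max(seg) - min(seg)
  if (rng < 1e-12) {
    out <- pulse * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (pulse - min(seg)) / rng
  attr(out, "degenerate") <- FALSE
  out
}

#' Detect dicrotic notch and diastolic peak within one pulse
#'
#' On a lightly smoothed copy, the dicrotic notch (DN) is the first
#' local minimum after the systolic peak and the diastolic peak (DP) the
#' first local maximum after the DN. When no interior minimum exists
#' (e.g. a pure monotone decay), the fallback places the DN at the
#' maximum of the second derivative between peak and offset with
#' DP = DN, and records the method. A decay with no curvature extremum
#' (flat second derivative) yields a failure flag.
#'
#' @param pulse One pulse (onset to offset).
#' @param fs Sampling rate (Hz).
#' @param peak Systolic peak index (default: global maximum).
#' @param offset Offset index (default: last sample).
#' @param smooth_n Moving-average width (samples) for the smoothed copy.
#' @return A `landmark_set`: `peak`, `dn`, `dp`, `offset`,
#'   `dn_method` (`"local_min"` or `"second_derivative_fallback"`),
#'   `failed`.
#' @export
detect_landmarks <- function(pulse, fs, peak = which.max(pulse),
                             offset = length(pulse), smooth_n = 3) {
  stopifnot(peak >= 1, peak < offset, offset <= length(pulse))
  sm <- smooth_ma(pulse, smooth_n)
  fail <- function() structure(list(peak = peak, dn = NA_integer_,
                                    dp = NA_integer_, offset = offset,
                                    dn_method = NA_character_,
                                    failed = TRUE),
                               class = "landmark_set")
  interior <- if (offset - peak >= 2) (peak + 1L):(offset - 1L)
              else integer(0)
  dn <- NA_integer_; dp <- NA_integer_; method <- "local_min"
  loc_min <- interior[sm[interior] < sm[interior - 1L] &
                        sm[interior] < sm[interior + 1L]]
  if (length(loc_min)) {
    dn <- loc_min[1]
    after <- if (offset - dn >= 2) (dn + 1L):(offset - 1L) else integer(0)
    loc_max <- after[sm[after] > sm[after - 1L] & sm[after] >= sm[after + 1L]]
    dp <- if (length(loc_max)) loc_max[1] else dn
  } else {
    if (length(interior) < 3) return(fail())
    d2 <- finite_derivative(finite_derivative(pulse, fs), fs)
    d2i <- d2[interior]
    # flat curvature (e.g. a linear decay) offers no fiducial point
    if (max(d2i) - min(d2i) < 1e-8 * fs^2) return(fail())
    dn <- interior[which.max(d2i)]
    dp <- dn
    method <- "second_derivative_fallback"
  }
  if (!(peak < dn && dn <= dp && dp < offset)) return(fail())
  structure(list(peak = peak, dn = dn, dp = dp, offset = offset,
                 dn_method = method, failed = FALSE),
            class = "landmark_set")
}

#' Finite-difference derivative
#'
#' Central differences in the interior and second-order one-sided
#' differences at the endpoints, scaled by `fs`; exact for sampled
#' polynomials up to degree 2.
#'
#' @param y Series.
#' @param fs Sampling rate (Hz).
#' @return Derivative series, same length.
#' @export
finite_derivative <- function(y, fs) {
  n <- length(y)
  if (n < 3) return(rep(NA_real_, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / 2
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / 2
  d * fs
}

trapz_area <- function(y, fs) sum((y[-1] + y[-length(y)]) / 2) / fs

#' Compute the 63-feature battery for one pulse
#'
#' For each of the three notch-centered segments (peak to DN, DN to DP,
#' DP to offset) and each derivative order (0, 1, 2; derivatives taken
#' on the full normalized pulse, then restricted to the segment):
#' segment length (seconds), slope ((last - first)/duration), minimum,
#' maximum, mean, median, and trapezoidal area over time. Segments with
#' fewer than 3 samples give `NA` for every statistic of that segment.
#'
#' @param pulse_norm Normalized pulse (see [normalize_pulse()]).
#' @param lm A `landmark_set`.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector over [feature_keys()].
#' @export
segment_features <- function(pulse_norm, lm, fs) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- stats::setNames(rep(NA_real_, 63L), .feature_keys)
  if (lm$failed) return(out)
  series <- list(as.numeric(pulse_norm))
  series[[2]] <- finite_derivative(series[[1]], fs)
  series[[3]] <- finite_derivative(series[[2]], fs)
  bounds <- list(c(lm$peak, lm$dn), c(lm$dn, lm$dp),
                 c(lm$dp, lm$offset))
  for (si in 1:3) {
    a <- bounds[[si]][1]; b <- bounds[[si]][2]
    if (b - a + 1 < 3) next
    dur <- (b - a) / fs
    for (d in 0:2) {
      v <- series[[d + 1]][a:b]
      # key order: stat fastest, then derivative order, then segment
      base <- ((si - 1L) * 3L + d) * 7L
      out[base + 1L] <- dur
      out[base + 2L] <- (v[length(v)] - v[1]) / dur
      out[base + 3L] <- min(v)
      out[base + 4L] <- max(v)
      out[base + 5L] <- mean(v)
      out[base + 6L] <- stats::median(v)
      out[base + 7L] <- trapz_area(v, fs)
    }
  }
  out
}

#' IQR outlier filter
#'
#' Removes values outside `[Q1 - k*IQR, Q3 + k*IQR]`; quartiles use the
#' linear-interpolation convention (R type 7).
#'
#' @param values Numeric vector (>= 4 values).
#' @param k IQR multiplier (default 1.5).
#' @return List with `values` (kept), `removed` (count) and `bounds`.
#' @export
iqr_filter <- function(values, k = 1.5) {
  stopifnot(length(values) >= 4)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
  keep <- values >= lo & values <= hi
  list(values = values[keep], removed = sum(!keep), bounds = c(lo, hi))
}

#' Per-pulse feature table for one record
#'
#' Segments the detrended record (reconciled two-detector result) but
#' computes features on the raw pressure pulses, since high-pass
#' detrending would strip the slow diastolic-runoff component the
#' features quantify. Raw pulses are denoised with a Savitzky-Golay
#' filter (order 3, 9 samples) before differentiation, then normalized
#' from peak to offset. Pulses whose landmark detection fails are
#' dropped.
#'
#' @param record A `waveform_record`.
#' @param max_pulses Cap on pulses used per record (for run-time
#'   control).
#' @param sg_n Savitzky-Golay window length in samples (0 disables
#'   denoising).
#' @return Data frame with `patient_id`, `pulse_id`, `label`, the 63
#'   feature columns, and `dn_method`.
#' @export
record_features <- function(record, max_pulses = Inf, sg_n = 9) {
  fs <- record$sampling_rate
  det <- detrend_abp(record$samples, fs)
  seg <- reconcile(detect_pulses_rule(det, fs), detect_pulses_alt(det, fs))
  raw <- if (sg_n > 0)
    as.numeric(signal::sgolayfilt(record$samples, p = 3, n = sg_n))
  else record$samples
  np <- min(length(seg$peaks), max_pulses)
  vals <- matrix(NA_real_, np, 63L, dimnames = list(NULL, .feature_keys))
  methods <- character(np)
  ok <- logical(np)
  for (i in seq_len(np)) {
    on <- seg$onsets[i]; pk <- seg$peaks[i]; off <- seg$offsets[i]
    pulse <- raw[on:off]
    lm <- detect_landmarks(pulse, fs, peak = pk - on + 1L)
    if (lm$failed) next
    pn <- normalize_pulse(pulse, pk - on + 1L)
    if (isTRUE(attr(pn, "degenerate"))) next
    vals[i, ] <- segment_features(pn, lm, fs)
    methods[i] <- lm$dn_method
    ok[i] <- TRUE
  }
  if (!any(ok)) return(NULL)
  cbind(data.frame(patient_id = record$patient_id,
                   pulse_id = which(ok), label = record$label,
                   dn_method = methods[ok], stringsAsFactors = FALSE),
        as.data.frame(vals[ok, , drop = FALSE]))
}

#' Feature table for a whole cohort
#'
#' @param records List of `waveform_record`s.
#' @param max_pulses Pulses used per record.
#' @param sg_n Savitzky-Golay denoising window (see
#'   [record_features()]).
#' @return Row-bound [record_features()] output.
#' @export
cohort_feature_table <- function(records, max_pulses = Inf, sg_n = 9) {
  do.call(rbind, lapply(records, record_features, max_pulses = max_pulses,
                        sg_n = sg_n))
}

shapiro_p <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 3) return(NA_real_)
  if (length(v) > 5000) v <- v[seq_len(5000)]
  if (stats::sd(v) < 1e-12) return(0)
  stats::shapiro.test(v)$p.value
}

# normality-gated two-sample test; returns list(test, p)
gated_test <- function(a, b, var_equal = TRUE) {
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  if (!is.na(pa) && !is.na(pb) && pa >= 0.05 && pb >= 0.05) {
    list(test = "t_test",
         p = stats::t.test(a, b, var.equal = var_equal)$p.value)
  } else {
    list(test = "u_test",
         p = suppressWarnings(
           stats::wilcox.test(a, b, exact = FALSE)$p.value))
  }
}

#' Two-group comparison of every feature
#'
#' Per feature: IQR-filter each outcome group, assess normality with the
#' Shapiro-Wilk test on both groups, then apply Student's t-test when
#' both are normal (p >= 0.05) and the Mann-Whitney U-test otherwise.
#' Two-sided, no multiplicity correction. Features with fewer than 3
#' finite values per group after filtering are skipped.
#'
#' @param features Feature table (e.g. [cohort_feature_table()]).
#' @param alpha Significance level.
#' @param iqr_k IQR multiplier for outlier removal.
#' @return Data frame: `feature`, `test_used`, `p_value`, `significant`,
#'   `direction` (sign of event minus non-event median),
#'   `median_event`, `median_nonevent`, `n_event`, `n_nonevent`,
#'   `removed`.
#' @export
compare_groups <- function(features, alpha = 0.05, iqr_k = 1.5) {
  keys <- intersect(feature_keys(), names(features))
  rows <- lapply(keys, function(k) {
    v <- features[[k]]; lab <- features$label
    ok <- is.finite(v)
    a <- v[ok & lab == 1]; b <- v[ok & lab == 0]
    if (length(a) < 4 || length(b) < 4) return(NULL)
    fa <- iqr_filter(a, iqr_k); fb <- iqr_filter(b, iqr_k)
    if (length(fa$values) < 3 || length(fb$values) < 3) return(NULL)
    if (stats::sd(c(fa$values, fb$values)) < 1e-12) {
      message("feature ", k, " degenerate after filtering; skipped")
      return(NULL)
    }
    ts <- gated_test(fa$values, fb$values)
    if (is.na(ts$p)) return(NULL)
    med_a <- stats::median(fa$values); med_b <- stats::median(fb$values)
    data.frame(feature = k, test_used = ts$test, p_value = ts$p,
               significant = ts$p < alpha,
               direction = sign(med_a - med_b),
               median_event = med_a, median_nonevent = med_b,
               n_event = length(fa$values), n_nonevent = length(fb$values),
               removed = fa$removed + fb$removed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aligned peak-to-offset pulse matrix
#'
#' Normalizes each segmented pulse from peak to offset and resamples the
#' peak-to-offset segment to `n_points`, giving pulses comparable point
#' by point. The dicrotic notch position of each pulse is mapped through
#' the resampling transform.
#'
#' @param records List of `waveform_record`s.
#' @param n_points Aligned length (default 300).
#' @param max_pulses Pulses per record.
#' @param sg_n Savitzky-Golay denoising window (see
#'   [record_features()]).
#' @return List: `pulses` (matrix, one row per pulse), `patient_id`,
#'   `label`, `notch_pos` (aligned notch index per pulse).
#' @export
aligned_pulses <- function(records, n_points = 300, max_pulses = Inf,
                           sg_n = 9) {
  mats <- list(); pid <- character(0); lab <- integer(0); np <- integer(0)
  for (record in records) {
    fs <- record$sampling_rate
    det <- detrend_abp(record$samples, fs)
    seg <- reconcile(detect_pulses_rule(det, fs),
                     detect_pulses_alt(det, fs))
    raw <- if (sg_n > 0)
      as.numeric(signal::sgolayfilt(record$samples, p = 3, n = sg_n))
    else record$samples
    nuse <- min(length(seg$peaks), max_pulses)
    for (i in seq_len(nuse)) {
      on <- seg$onsets[i]; pk <- seg$peaks[i]; off <- seg$offsets[i]
      pulse <- raw[on:off]
      pk_rel <- pk - on + 1L
      lm <- detect_landmarks(pulse, fs, peak = pk_rel)
      if (lm$failed) next
      pn <- normalize_pulse(pulse, pk_rel)
      if (isTRUE(attr(pn, "degenerate"))) next
      segment <- pn[pk_rel:length(pn)]
      if (length(segment) < 3) next
      mats[[length(mats) + 1L]] <- resample_linear(segment, n_points)
      pid <- c(pid, record$patient_id)
      lab <- c(lab, record$label)
      np <- c(np, resample_map_index(lm$dn - pk_rel + 1L,
                                     length(segment), n_points))
    }
  }
  list(pulses = do.call(rbind, mats), patient_id = pid, label = lab,
       notch_pos = np)
}

#' Point-by-point two-group comparison of aligned pulses
#'
#' Pulses are first averaged within patient (avoiding pseudo-replication
#' across a patient's beats); at each aligned position the same
#' normality-gated two-group test as [compare_groups()] is applied.
#'
#' @param pulses Matrix of aligned pulses (rows) from
#'   [aligned_pulses()].
#' @param patient_ids,labels Per-row metadata.
#' @param alpha Significance level.
#' @return List: `p_values` (per position), `significant` (positions
#'   below `alpha`), `alpha`.
#' @export
pointwise_compare <- function(pulses, patient_ids, labels, alpha = 0.05) {
  stopifnot(nrow(pulses) == length(patient_ids),
            nrow(pulses) == length(labels))
  ids <- unique(patient_ids)
  pat_lab <- vapply(ids, function(id)
    labels[match(id, patient_ids)], numeric(1))
  if (sum(pat_lab == 1) < 2 || sum(pat_lab == 0) < 2)
    stop("need at least 2 patients per group")
  M <- t(vapply(ids, function(id)
    colMeans(pulses[patient_ids == id, , drop = FALSE]),
    numeric(ncol(pulses))))
  pv <- vapply(seq_len(ncol(M)), function(j)
    gated_test(M[pat_lab == 1, j], M[pat_lab == 0, j])$p, numeric(1))
  list(p_values = pv, significant = which(pv < alpha), alpha = alpha)
}
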