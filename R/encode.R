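# Signal-to-image encodings of normalized pulse instances: Gramian
# angular summation field (GASF), Markov transition field (MTF),
# recurrence plot (RP), spectrogram (SPEC) and direct raw pulse plotting
# (DRP). All encoders are pure functions: identical input and
# configuration give bit-identical output.

#' Encoder configuration
#'
#' @param encoder One of `"GASF"`, `"MTF"`, `"RP"`, `"SPEC"`, `"DRP"`.
#' @param mtf_bins Number of quantile bins for the MTF (>= 2).
#' @param rp_threshold_frac Recurrence threshold as a fraction of the
#'   maximum pairwise distance, or `NA` for the unthresholded distance
#'   matrix.
#' @param stft_window,stft_hop Spectrogram window and hop (samples);
#'   Hann window.
#' @param log_magnitude Return log(1 + magnitude) spectrograms.
#' @param raster_size DRP raster side (pixels, >= 32).
#' @param line_width DRP line width (pixels).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(encoder = "DRP", mtf_bins = 8,
                           rp_threshold_frac = 0.1, stft_window = 64,
                           stft_hop = 16, log_magnitude = FALSE,
                           raster_size = 224, line_width = 1) {
  encoder <- match.arg(encoder, c("GASF", "MTF", "RP", "SPEC", "DRP"))
  stopifnot(mtf_bins >= 2, raster_size >= 32, line_width >= 1,
            stft_window >= 2, stft_hop >= 1)
  structure(list(encoder = encoder, mtf_bins = mtf_bins,
                 rp_threshold_frac = rp_threshold_frac,
                 stft_window = stft_window, stft_hop = stft_hop,
                 log_magnitude = log_magnitude,
                 raster_size = raster_size, line_width = line_width),
            class = "encoder_config")
}

instance_values <- function(x) {
  if (inherits(x, "normalized_instance")) x$values else as.numeric(x)
}

new_image <- function(pixels, encoder, instance_id = NA_character_,
                      degenerate = FALSE) {
  structure(list(pixels = pixels, encoder = encoder,
                 instance_id = instance_id, degenerate = degenerate),
            class = "encoded_image")
}

#' Gramian angular summation field
#'
#' Rescales the unit-interval series to [-1, 1] (`x~ = 2x - 1`), takes
#' angular coordinates `phi_i = arccos(x~_i)` and forms
#' `pixels[i, j] = cos(phi_i + phi_j)`. The result is symmetric with
#' diagonal `2 x~_i^2 - 1`.
#'
#' @param x A `normalized_instance` or numeric vector with values in
#'   [0, 1].
#' @return An `encoded_image` with an n-by-n pixel matrix.
#' @export
encode_gasf <- function(x) {
  v <- instance_values(x)
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("GASF input must lie in [0, 1]")
  v <- pmin(1, pmax(0, v))
  xt <- 2 * v - 1
  phi <- acos(xt)
  px <- cos(outer(phi, phi, "+"))
  new_image(px, "GASF", if (inherits(x, "normalized_instance"))
    x$patient_id else NA_character_)
}

#' Markov transition field
#'
#' Values are assigned to `bins` quantile bins; the first-order
#' transition matrix `W` over consecutive time points is row-normalized
#' (rows with no outgoing transitions are set to the uniform row), and
#' `pixels[i, j] = W[bin(i), bin(j)]`.
#'
#' @param x A `normalized_instance` or numeric vector.
#' @param bins Number of quantile bins.
#' @return An `encoded_image`; `degenerate` is set when all values are
#'   identical (the image is then all ones).
#' @export
encode_mtf <- function(x, bins = 8) {
  v <- instance_values(x)
  n <- length(v)
  stopifnot(n >= 2, bins >= 2)
  if (max(v) - min(v) < 1e-12) {
    return(new_image(matrix(1, n, n), "MTF", degenerate = TRUE))
  }
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                        type = 7, names = FALSE)
  qs <- unique(qs)
  nb <- length(qs) - 1L
  b <- findInterval(v, qs, rightmost.closed = TRUE, all.inside = TRUE)
  W <- matrix(0, nb, nb)
  for (t in seq_len(n - 1L)) W[b[t], b[t + 1L]] <- W[b[t], b[t + 1L]] + 1
  rs <- rowSums(W)
  for (r in seq_len(nb)) {
    W[r, ] <- if (rs[r] > 0) W[r, ] / rs[r] else rep(1 / nb, nb)
  }
  new_image(W[b, b, drop = FALSE], "MTF")
}

#' Recurrence plot
#'
#' Pairwise distance matrix `D[i, j] = |x_i - x_j|`. In thresholded mode
#' pixels are 1 where `D <= eps` with
#' `eps = rp_threshold_frac * max(D)`, else 0; with
#' `rp_threshold_frac = NA` the raw distance matrix is returned.
#'
#' @param x A `normalized_instance` or numeric vector.
#' @param cfg An [encoder_config()]; only `rp_threshold_frac` is used.
#' @return An `encoded_image`.
#' @export
encode_rp <- function(x, cfg = encoder_config("RP")) {
  v <- instance_values(x)
  stopifnot(length(v) >= 2)
  D <- abs(outer(v, v, "-"))
  frac <- cfg$rp_threshold_frac
  px <- if (is.na(frac)) D else (D <= frac * max(D)) * 1
  new_image(px, "RP")
}

#' Spectrogram
#'
#' Magnitude of the short-time Fourier transform with a Hann window:
#' frames of `stft_window` samples advanced by `stft_hop`, one column per
#' frame, rows covering 0 to the Nyquist bin.
#'
#' @param x A `normalized_instance` or numeric vector.
#' @param cfg An [encoder_config()]; uses `stft_window`, `stft_hop`,
#'   `log_magnitude`.
#' @return An `encoded_image` with a (window/2 + 1)-by-frames pixel
#'   matrix.
#' @export
encode_spec <- function(x, cfg = encoder_config("SPEC")) {
  v <- instance_values(x)
  w <- cfg$stft_window; hop <- cfg$stft_hop
  if (w > length(v)) stop("stft_window exceeds series length")
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))  # Hann
  starts <- seq(1, length(v) - w + 1, by = hop)
  nf <- w %/% 2 + 1L
  px <- vapply(starts, function(s) {
    frame <- v[s:(s + w - 1)] * win
    Mod(stats::fft(frame))[seq_len(nf)]
  }, numeric(nf))
  px <- matrix(px, nrow = nf)
  if (cfg$log_magnitude) px <- log1p(px)
  new_image(px, "SPEC")
}

#' Direct raw pulse plot
#'
#' Renders the instance polyline axis-free onto a square monochrome
#' raster: sample index maps linearly to columns, value to rows (value 1
#' at the top), line pixels are 1 on a 0 background. Rendering is
#' deterministic (no graphics device), so rasters are bit-exact for a
#' fixed configuration.
#'
#' @param x A `normalized_instance` or numeric vector with values in
#'   [0, 1].
#' @param cfg An [encoder_config()]; uses `raster_size` and
#'   `line_width`.
#' @return An `encoded_image` with a `raster_size`-square 0/1 matrix.
#' @export
encode_drp <- function(x, cfg = encoder_config("DRP")) {
  v <- instance_values(x)
  n <- length(v)
  sz <- cfg$raster_size
  stopifnot(sz >= 32, n >= 2)
  col_of <- function(i) 1 + (i - 1) * (sz - 1) / (n - 1)
  row_of <- function(val) 1 + (1 - val) * (sz - 1)  # value 1 -> top row
  px <- matrix(0, sz, sz)
  # draw each segment by stepping at sub-pixel resolution
  for (i in seq_len(n - 1L)) {
    c0 <- col_of(i); c1 <- col_of(i + 1)
    r0 <- row_of(v[i]); r1 <- row_of(v[i + 1])
    steps <- max(2L, ceiling(max(abs(c1 - c0), abs(r1 - r0))) * 2L)
    tt <- seq(0, 1, length.out = steps)
    rr <- round(r0 + tt * (r1 - r0))
    cc <- round(c0 + tt * (c1 - c0))
    px[cbind(rr, cc)] <- 1
  }
  lw <- as.integer(cfg$line_width)
  if (lw > 1) {
    half <- lw %/% 2
    base <- px
    for (dr in -half:half) if (dr != 0) {
      shifted <- matrix(0, sz, sz)
      src <- seq_len(sz) - dr
      ok <- src >= 1 & src <= sz
      shifted[which(ok), ] <- base[src[ok], ]
      px <- pmax(px, shifted)
    }
  }
  new_image(px, "DRP")
}

#' Encode an instance with the configured encoder
#'
#' @param x A `normalized_instance` or numeric vector.
#' @param cfg An [encoder_config()].
#' @return An `encoded_image`.
#' @export
encode_instance <- function(x, cfg = encoder_config()) {
  switch(cfg$encoder,
    GASF = encode_gasf(x),
    MTF = encode_mtf(x, cfg$mtf_bins),
    RP = encode_rp(x, cfg),
    SPEC = encode_spec(x, cfg),
    DRP = encode_drp(x, cfg)
  )
}
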