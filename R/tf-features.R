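#' Notch-filter an EEG recording
#'
#' Removes power-line noise with a second-order IIR notch (a biquad with a
#' transfer-function zero exactly on the line frequency). The -3 dB bandwidth
#' defaults to 1 Hz, which keeps the passband within 1 dB beyond 2 Hz from the
#' notch.
#'
#' @param rec An [eeg_recording()].
#' @param line_hz Line frequency in Hz (must be below Nyquist).
#' @param bw_hz -3 dB bandwidth of the notch in Hz.
#' @return The filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, line_hz = 50, bw_hz = 1) {
  if (line_hz >= rec$rate_hz / 2) abort("`line_hz` must be below Nyquist.")
  cf <- notch_coefficients(line_hz, rec$rate_hz, bw_hz)
  out <- rec
  for (j in seq_len(ncol(rec$samples))) {
    out$samples[, j] <- notch_apply(rec$samples[, j], cf)$y
  }
  out
}

# RBJ biquad notch coefficients, normalized (a0 = 1).
notch_coefficients <- function(line_hz, rate_hz, bw_hz = 1) {
  w0 <- 2 * pi * line_hz / rate_hz
  q <- line_hz / bw_hz
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(b = c(1, -2 * cos(w0), 1) / a0,
       a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
}

# Direct-form II transposed biquad with explicit state, so the streaming
# engine can filter packet-by-packet and match a one-shot batch filter
# sample for sample.
notch_apply <- function(x, cf, state = c(0, 0)) {
  b <- cf$b; a <- cf$a
  z1 <- state[1]; z2 <- state[2]
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    xn <- x[n]
    yn <- b[1] * xn + z1
    z1 <- b[2] * xn - a[2] * yn + z2
    z2 <- b[3] * xn - a[3] * yn
    y[n] <- yn
  }
  list(y = y, state = c(z1, z2))
}

#' Stockwell (S-) transform of a recording
#'
#' Computes the amplitude of the S-transform at 1 Hz frequency steps with the
#' classic frequency-dependent Gaussian window (sigma = 1/f seconds, unit
#' area). The transform is circular; it is evaluated as a cross-correlation of
#' the demodulated signal with the (wrapped) window, accelerated by FFTs.
#'
#' With a finite `support_s` the window is truncated at `+- support_s` seconds
#' and renormalized, which makes every column at least `support_s` from both
#' record ends depend only on in-record samples. The streaming engine and the
#' batch featurization pipeline rely on that locality.
#'
#' @param rec An [eeg_recording()] (first channel is analysed) or a numeric
#'   vector together with `rate_hz`.
#' @param fmin_hz,fmax_hz Analysis range; frequencies `fmin:fmax` in 1 Hz steps.
#' @param support_s Half-support of the Gaussian window in seconds
#'   (`Inf` = classic untruncated window).
#' @param rate_hz Sampling rate, only when `rec` is a plain vector.
#' @return A `tf_map`: list with `freqs_hz`, `times_s` and the non-negative
#'   `amplitude` matrix (frequency x time).
#' @export
stockwell <- function(rec, fmin_hz = 1, fmax_hz = 40, support_s = Inf,
                      rate_hz = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$samples[, 1L]
    fs <- rec$rate_hz
  } else {
    x <- as.numeric(rec)
    if (is.null(rate_hz)) abort("`rate_hz` required for a plain vector.")
    fs <- rate_hz
  }
  if (fmin_hz < 1) abort("`fmin_hz` must be >= 1.")
  if (fmax_hz > fs / 2) abort("`fmax_hz` must not exceed Nyquist.")
  n <- length(x)
  dur <- n / fs
  if (dur < 2 / fmin_hz) abort("record shorter than the analysis window.")
  if (is.finite(support_s) && 2 * support_s > dur) {
    abort("window support longer than the record.")
  }
  freqs <- seq(fmin_hz, fmax_hz, by = 1)
  amp <- matrix(0, nrow = length(freqs), ncol = n)
  tloc <- seq_len(n) - 1L
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    g <- st_window(f, n, fs, support_s)
    y <- x * exp(-2i * pi * f * tloc / fs)
    s <- fft(fft(y) * Re(fft(g)), inverse = TRUE) / n
    amp[i, ] <- Mod(s)
  }
  structure(list(freqs_hz = freqs, times_s = tloc / fs, amplitude = amp,
                 rate_hz = fs),
            class = "tf_map")
}

# Discrete Gaussian window of sd 1/f s centered at lag 0, wrapped over the
# n-sample circle (or truncated at +- support_s), normalized to sum 1.
st_window <- function(f, n, fs, support_s = Inf) {
  lag <- 0:(n - 1L)
  circ <- pmin(lag, n - lag) / fs  # circular lag distance in seconds
  if (is.finite(support_s)) {
    g <- ifelse(circ <= support_s, exp(-0.5 * (circ * f)^2), 0)
  } else {
    # wrap a few periodic images; the Gaussian dies off within one circle
    tsec <- ifelse(lag <= n / 2, lag, lag - n) / fs
    g <- 0
    for (k in -2:2) g <- g + exp(-0.5 * ((tsec + k * n / fs) * f)^2)
  }
  g / sum(g)
}

#' Equal-area frequency banding of a log-mean spectrum
#'
#' Divides a 1 Hz-resolution log-mean spectrum into `n_bands` contiguous bands
#' of (approximately) equal area. Edges fall on the 1 Hz grid; each cut is
#' placed at the grid point whose cumulative area is closest to the ideal
#' multiple of `total/n_bands`, with collisions pushed left-to-right.
#'
#' @param log_mean_spectrum Numeric vector over 1 Hz bins (must be positive).
#' @param n_bands Number of bands (>= 2).
#' @param freqs_hz Frequencies of the bins; defaults to `1:length(spectrum)`.
#'   Bin `f` covers `[f, f + 1)` Hz.
#' @return A [band_scheme()].
#' @export
equal_area_bands <- function(log_mean_spectrum, n_bands = 10L, freqs_hz = NULL) {
  s <- as.numeric(log_mean_spectrum)
  if (n_bands < 2L) abort("`n_bands` must be >= 2.")
  if (length(s) < n_bands) abort("fewer frequency bins than bands.")
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("spectrum must be strictly positive (apply a log offset first).")
  }
  if (is.null(freqs_hz)) freqs_hz <- seq_along(s)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  cuts <- integer(n_bands - 1L)
  prev <- 0L
  for (k in seq_len(n_bands - 1L)) {
    target <- k * total / n_bands
    j <- which.min(abs(cum - target))
    j <- max(j, prev + 1L)                       # keep edges strictly increasing
    j <- min(j, length(s) - (n_bands - 1L - k) - 1L)  # leave room for later cuts
    cuts[k] <- j
    prev <- j
  }
  edges <- c(freqs_hz[1L], freqs_hz[cuts + 1L], freqs_hz[length(s)] + 1)
  band_scheme(edges)
}

#' Collapse a time-frequency map into band rows
#'
#' Each band row is the mean of the amplitude rows whose frequency lies in
#' the band's half-open interval `[low, high)`.
#'
#' @param tf A `tf_map` from [stockwell()].
#' @param scheme A [band_scheme()] within the map's frequency range.
#' @return Numeric matrix (bands x time) at the map's time resolution.
#' @export
collapse_to_bands <- function(tf, scheme) {
  e <- scheme$edges_hz
  if (min(e) < min(tf$freqs_hz) || max(e) - 1 > max(tf$freqs_hz)) {
    abort("band scheme extends beyond the map's frequency range.")
  }
  out <- matrix(0, nrow = n_bands(scheme), ncol = ncol(tf$amplitude))
  for (b in seq_len(n_bands(scheme))) {
    rows <- which(tf$freqs_hz >= e[b] & tf$freqs_hz < e[b + 1L])
    if (length(rows) == 0L) abort(sprintf("band %d contains no frequency row.", b))
    out[b, ] <- colMeans(tf$amplitude[rows, , drop = FALSE])
  }
  out
}

#' Resample a (matrix x time) series to 4 Hz
#'
#' Downsampling (source rate above 4 Hz) takes the mean over consecutive
#' 250 ms blocks; block boundaries may fall between samples (e.g. 62.5 samples
#' at 250 Hz), in which case each block takes the samples whose index falls in
#' `[i * rate/4, (i+1) * rate/4)`. Upsampling (source rate below 4 Hz, e.g.
#' BOLD at TR = 3 s) linearly interpolates onto the 4 Hz grid; 4 Hz must then
#' be an integer multiple of the source rate.
#'
#' @param series Numeric matrix (rows x time) or vector.
#' @param rate_hz Source sampling rate.
#' @return Matrix (or vector) at 4 Hz.
#' @export
resample_to_4hz <- function(series, rate_hz) {
  vec <- is.vector(series)
  if (vec) series <- matrix(series, nrow = 1L)
  n <- ncol(series)
  if (rate_hz == 4) {
    out <- series
  } else if (rate_hz > 4) {
    r <- rate_hz / 4
    nb <- floor(n / r)
    if (nb < 1L) abort("series too short to downsample.")
    out <- matrix(0, nrow = nrow(series), ncol = nb)
    for (i in seq_len(nb)) {
      idx <- (floor((i - 1) * r) + 1L):floor(i * r)
      out[, i] <- rowMeans(series[, idx, drop = FALSE])
    }
  } else {
    ratio <- 4 / rate_hz
    if (abs(ratio - round(ratio)) > 1e-9) {
      abort("source and target rates are not commensurate.")
    }
    src_t <- (seq_len(n) - 1L) / rate_hz
    tgt_t <- seq(0, src_t[n], by = 0.25)
    out <- t(apply(series, 1L, function(v) approx(src_t, v, xout = tgt_t)$y))
  }
  if (vec) out[1L, ] else out
}

#' Normalize band powers against a rest reference
#'
#' Applies the shared affine contract `(value - ref mean) / ref sd` per band;
#' the same contract is used offline and online so streamed and batch features
#' are identical.
#'
#' @param series A [band_powers()] object.
#' @param ref A [rest_reference()] with matching band count.
#' @return The normalized [band_powers()].
#' @export
normalize_bands <- function(series, ref) {
  if (length(ref$mean_per_band) != nrow(series$values)) {
    abort("reference band count does not match the series.")
  }
  out <- series
  out$values <- (series$values - ref$mean_per_band) / ref$sd_per_band
  out$normalization <- "reference_normalized"
  out
}

#' Invert a rest-reference normalization
#'
#' @inheritParams normalize_bands
#' @return The raw-scale [band_powers()].
#' @export
denormalize_bands <- function(series, ref) {
  out <- series
  out$values <- series$values * ref$sd_per_band + ref$mean_per_band
  out$normalization <- "raw"
  out
}

#' Log-mean 1 Hz spectrum of a recording
#'
#' Mean over time of `log(amplitude + eps)` of the Stockwell transform,
#' exponentiated back so the result is a positive spectrum suitable for
#' [equal_area_bands()].
#'
#' @param rec An [eeg_recording()].
#' @param fmin_hz,fmax_hz Analysis range.
#' @param eps Log offset guarding against zero amplitude.
#' @return Numeric vector over `fmin:fmax` Hz with a `freqs_hz` attribute.
#' @export
log_mean_spectrum <- function(rec, fmin_hz = 1, fmax_hz = 40, eps = 1e-12) {
  tf <- stockwell(rec, fmin_hz, fmax_hz)
  s <- exp(rowMeans(log(tf$amplitude + eps)))
  attr(s, "freqs_hz") <- tf$freqs_hz
  s
}

#' Full offline featurization pipeline
#'
#' notch -> Stockwell (truncated window) -> collapse to bands -> 4 Hz block
#' means -> optional rest-reference normalization. Columns within
#' `edge_exclude_s` of either record end are dropped (they depend on samples
#' outside the record through the analysis window); the returned time stamps
#' are absolute seconds from record start, so batch features align exactly
#' with streamed features.
#'
#' @param rec An [eeg_recording()].
#' @param scheme The [band_scheme()] to collapse into.
#' @param ref Optional [rest_reference()]; if given the output is normalized.
#' @param fmin_hz,fmax_hz Analysis range in Hz.
#' @param line_hz Notch frequency (`NULL` to skip the notch).
#' @param support_s Stockwell window half-support in seconds.
#' @param edge_exclude_s Edge margin to drop, in seconds.
#' @return A [band_powers()] object at 4 Hz.
#' @export
featurize_recording <- function(rec, scheme, ref = NULL, fmin_hz = 1,
                                fmax_hz = 40, line_hz = 50, support_s = 1,
                                edge_exclude_s = 1) {
  if (!is.null(line_hz)) rec <- notch_filter(rec, line_hz)
  tf <- stockwell(rec, fmin_hz, fmax_hz, support_s = support_s)
  bands <- collapse_to_bands(tf, scheme)
  bp <- resample_to_4hz(bands, rec$rate_hz)
  times <- (seq_len(ncol(bp)) - 1L) / 4
  keep <- times >= edge_exclude_s &
    (times + 0.25) <= (nrow(rec$samples) / rec$rate_hz - edge_exclude_s)
  out <- band_powers(bp[, keep, drop = FALSE], scheme, times_s = times[keep])
  if (!is.null(ref)) out <- normalize_bands(out, ref)
  out
}
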