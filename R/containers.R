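#' Single- or multi-channel EEG recording
#'
#' A light container for raw EEG. Samples are stored as a numeric matrix with
#' one column per channel (microvolts); downstream modeling uses a single
#' channel (conventionally Pz).
#'
#' @param samples Numeric vector (one channel) or matrix (samples x channels).
#' @param rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param subject_id,session_id Identifier strings.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate_hz, channel_labels = "Pz",
                          subject_id = "", session_id = "") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  if (length(channel_labels) != ncol(samples)) {
    abort("`channel_labels` must name every channel.")
  }
  structure(
    list(samples = samples, rate_hz = rate_hz,
         channel_labels = as.character(channel_labels),
         subject_id = subject_id, session_id = session_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s) [%s]\n",
              ncol(x$samples), nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz,
              paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a recording as a numeric vector
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label; defaults to the first channel.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(rec, channel = NULL) {
  if (is.null(channel)) return(rec$samples[, 1L])
  i <- match(channel, rec$channel_labels)
  if (is.na(i)) abort(sprintf("channel '%s' not present", channel))
  rec$samples[, i]
}

#' Contiguous frequency-band scheme
#'
#' Bands are half-open intervals `[low, high)` on a 1 Hz frequency grid,
#' defined by `n_bands + 1` strictly increasing edges.
#'
#' @param edges_hz Ascending numeric vector of band edges in Hz.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(edges_hz) {
  edges_hz <- as.numeric(edges_hz)
  if (length(edges_hz) < 3L || any(diff(edges_hz) <= 0)) {
    abort("`edges_hz` must be >= 3 strictly increasing values.")
  }
  structure(list(edges_hz = edges_hz), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> %d bands over [%g, %g) Hz\n",
              n_bands(x), min(x$edges_hz), max(x$edges_hz)))
  cat(" edges:", paste(signif(x$edges_hz, 4), collapse = " "), "\n")
  invisible(x)
}

#' Number of bands in a scheme
#' @param scheme A [band_scheme()].
#' @return Integer count of bands.
#' @export
n_bands <- function(scheme) length(scheme$edges_hz) - 1L

#' Uniform band scheme over a frequency range
#'
#' @param fmin_hz,fmax_hz Range limits (bands cover `[fmin, fmax + 1)`).
#' @param n Number of bands.
#' @return A [band_scheme()] with equally wide bands.
#' @export
uniform_scheme <- function(fmin_hz = 1, fmax_hz = 40, n = 10L) {
  band_scheme(seq(fmin_hz, fmax_hz + 1, length.out = n + 1L))
}

#' Rest-period reference statistics for band-power normalization
#'
#' @param mean_per_band,sd_per_band Numeric vectors, one value per band.
#' @param source_session Identifier of the session the reference comes from.
#' @return An object of class `rest_reference`.
#' @export
rest_reference <- function(mean_per_band, sd_per_band, source_session = "") {
  if (length(mean_per_band) != length(sd_per_band)) {
    abort("reference mean and sd must have one value per band.")
  }
  if (any(!is.finite(sd_per_band)) || any(sd_per_band <= 0)) {
    abort("reference sd must be positive in every band (degenerate rest data).")
  }
  structure(list(mean_per_band = as.numeric(mean_per_band),
                 sd_per_band = as.numeric(sd_per_band),
                 source_session = source_session),
            class = "rest_reference")
}

#' Band-power series container
#'
#' A bands x time matrix at 4 Hz with its band scheme, absolute time stamps
#' (seconds, start of each 250 ms block) and a normalization flag.
#'
#' @param values Numeric matrix (bands x time).
#' @param scheme The [band_scheme()] the rows follow.
#' @param times_s Numeric vector of column time stamps in seconds.
#' @param normalization `"raw"` or `"reference_normalized"`.
#' @param rate_hz Sampling rate of the columns (4 Hz).
#' @return An object of class `band_powers`.
#' @export
band_powers <- function(values, scheme, times_s = NULL,
                        normalization = c("raw", "reference_normalized"),
                        rate_hz = 4) {
  normalization <- match.arg(normalization)
  if (nrow(values) != n_bands(scheme)) {
    abort("`values` must have one row per band of `scheme`.")
  }
  if (is.null(times_s)) times_s <- (seq_len(ncol(values)) - 1L) / rate_hz
  if (length(times_s) != ncol(values)) abort("`times_s` must match columns.")
  structure(list(values = values, scheme = scheme, times_s = as.numeric(times_s),
                 normalization = normalization, rate_hz = rate_hz),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> %d bands x %d cols @ %g Hz (%s)\n",
              nrow(x$values), ncol(x$values), x$rate_hz, x$normalization))
  invisible(x)
}

#' Paired band-power / BOLD session
#'
#' Holds the normalized 10-band x time matrix at 4 Hz and the z-scored BOLD
#' series for one session. The BOLD vector is aligned so that `bold[i]`
#' corresponds to band-power column `i + 47` (a full 12-s history exists for
#' every BOLD point).
#'
#' @param bands Numeric matrix (bands x time) of normalized band power at 4 Hz.
#' @param bold Numeric vector, z-scored BOLD at 4 Hz, length `ncol(bands) - 47`.
#' @param scheme The session's [band_scheme()].
#' @param subject_id,session_id Identifier strings.
#' @return An object of class `session_dataset`.
#' @export
session_dataset <- function(bands, bold, scheme, subject_id = "", session_id = "") {
  if (nrow(bands) != n_bands(scheme)) abort("band count mismatch with scheme.")
  if (length(bold) != ncol(bands) - 47L) {
    abort(sprintf("`bold` must have length ncol(bands) - 47 (%d), got %d.",
                  ncol(bands) - 47L, length(bold)))
  }
  v <- var(bold)
  if (is.finite(v) && abs(v - 1) > 1e-6) {
    abort("`bold` must be z-scored (unit variance).")
  }
  structure(list(bands = bands, bold = as.numeric(bold), scheme = scheme,
                 subject_id = subject_id, session_id = session_id),
            class = "session_dataset")
}

#' @export
print.session_dataset <- function(x, ...) {
  cat(sprintf("<session_dataset> %s/%s: %d bands x %d cols, %d BOLD points\n",
              x$subject_id, x$session_id, nrow(x$bands), ncol(x$bands),
              length(x$bold)))
  invisible(x)
}
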