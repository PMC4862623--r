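#' Simulation specification for paired EEG/BOLD sessions
#'
#' Defines the study conditions for the synthetic generator: a majority group
#' of sessions sharing one true coefficient matrix ("positives") plus a
#' minority of outlier sessions with independently perturbed matrices.
#'
#' @param n_sessions Total number of sessions.
#' @param n_positive Number of sessions sharing the positive-group matrix.
#' @param duration_s Session duration in seconds (>= 60).
#' @param eeg_rate_hz Raw EEG sampling rate (default 250 Hz).
#' @param seed Master seed; every session derives its own sub-seed from it.
#' @param outlier_perturbation Scale of the zero-mean Gaussian perturbation
#'   added to the positive coefficient matrix for outlier sessions (the
#'   perturbed matrix is renormalized to the positive matrix's Frobenius
#'   norm, so one scalar controls cluster separation).
#' @param snr Signal-to-noise variance ratio of the simulated BOLD.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_sessions = 15L, n_positive = 10L, duration_s = 300,
                     eeg_rate_hz = 250, seed = 1L, outlier_perturbation = 1,
                     snr = 1) {
  stopifnot_scalar_num(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_num(eeg_rate_hz, "eeg_rate_hz", positive = TRUE)
  stopifnot_scalar_num(outlier_perturbation, "outlier_perturbation", nonneg = TRUE)
  stopifnot_scalar_num(snr, "snr", positive = TRUE)
  if (n_positive > n_sessions) abort("`n_positive` must be <= `n_sessions`.")
  if (duration_s < 60) abort("`duration_s` must be >= 60 s (one 12-s delay window plus usable data).")
  structure(list(n_sessions = as.integer(n_sessions),
                 n_positive = as.integer(n_positive),
                 duration_s = duration_s, eeg_rate_hz = eeg_rate_hz,
                 seed = as.integer(seed),
                 outlier_perturbation = outlier_perturbation, snr = snr),
            class = "sim_spec")
}

#' Ground-truth EEG-to-BOLD mapping for one synthetic session
#'
#' @param coeffs Numeric matrix (bands x delays) of true weights.
#' @param scheme The [band_scheme()] the rows follow.
#' @param noise_sd Realized BOLD noise standard deviation (>= 0).
#' @param session_group `"positive"` or `"outlier"`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(coeffs, scheme, noise_sd = 0,
                         session_group = c("positive", "outlier")) {
  session_group <- match.arg(session_group)
  if (nrow(coeffs) != n_bands(scheme)) abort("coeffs rows must match band count.")
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(coeffs = coeffs, scheme = scheme, noise_sd = noise_sd,
                 session_group = session_group),
            class = "ground_truth")
}

# Slowly varying log-normal envelopes at 4 Hz: Gaussian noise smoothed with a
# 1-s sd kernel (autocorrelation time ~2 s), exponentiated.
sim_envelopes <- function(n_bands, n4, seed, base_uV = 10) {
  with_seed(seed, {
    env <- matrix(0, n_bands, n4)
    for (b in seq_len(n_bands)) {
      z <- rnorm(n4)
      env[b, ] <- base_uV * exp(0.35 * gauss_smooth(z, sd_samples = 4))
    }
    env
  })
}

# Circular Gaussian smoothing, renormalized to unit variance.
gauss_smooth <- function(z, sd_samples) {
  n <- length(z)
  lag <- 0:(n - 1L)
  d <- pmin(lag, n - lag)
  k <- exp(-0.5 * (d / sd_samples)^2)
  k <- k / sum(k)
  s <- Re(fft(fft(z) * fft(k), inverse = TRUE)) / n
  s / sd(s)
}

#' Simulate one synthetic EEG recording
#'
#' Builds a single-channel recording as a sum of band-limited noise carriers,
#' one per band of the scheme, each multiplied by a slowly varying log-normal
#' amplitude envelope. Envelopes are generated directly at 4 Hz (the model
#' resolution) and linearly upsampled to the EEG rate, and are attached to the
#' recording (`attr(rec, "envelopes")`) for oracle use.
#'
#' @param spec A [sim_spec()].
#' @param session_index Session number (drives the per-session sub-seed).
#' @param scheme Band scheme of the carriers; defaults to ten uniform bands
#'   over 1-41 Hz.
#' @param band_gains Per-band multiplicative gains (a zero silences a carrier).
#' @return An [eeg_recording()] with `envelopes` and `scheme` attributes.
#' @export
simulate_eeg <- function(spec, session_index = 1L, scheme = uniform_scheme(),
                         band_gains = rep(1, n_bands(scheme))) {
  if (spec$duration_s < 12) abort("duration too short for one 12-s window.")
  fs <- spec$eeg_rate_hz
  n <- round(spec$duration_s * fs)
  n4 <- round(spec$duration_s * 4)
  seed <- derive_seed(spec$seed, session_index)
  env <- sim_envelopes(n_bands(scheme), n4, seed) * band_gains
  x <- with_seed(derive_seed(seed, 1L), {
    t4 <- (seq_len(n4) - 1L) / 4
    thi <- (seq_len(n) - 1L) / fs
    acc <- numeric(n)
    for (b in seq_len(n_bands(scheme))) {
      carrier <- bandlimited_noise(n, fs, scheme$edges_hz[b], scheme$edges_hz[b + 1L])
      e_hi <- approx(t4, env[b, ], xout = thi, rule = 2)$y
      acc <- acc + e_hi * carrier
    }
    acc
  })
  rec <- eeg_recording(x, fs, channel_labels = "Pz",
                       session_id = sprintf("s%02d", session_index))
  attr(rec, "envelopes") <- env
  attr(rec, "scheme") <- scheme
  rec
}

# Unit-RMS constant-modulus carrier confined to [lo, hi) Hz: a cosine whose
# instantaneous frequency wanders slowly inside the band. The constant
# modulus keeps the carrier's short-time amplitude fixed, so the band power
# seen by the time-frequency front end tracks the imposed envelope rather
# than the carrier's own amplitude fluctuations.
bandlimited_noise <- function(n, fs, lo, hi) {
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2 * 0.7          # keep the wander off the band edges
  s <- gauss_smooth(rnorm(n), sd_samples = fs)  # ~1 s correlation time
  finst <- ctr + half * tanh(s / 1.5)
  phase <- 2 * pi * cumsum(finst) / fs
  sqrt(2) * cos(phase + stats::runif(1) * 2 * pi)
}

#' Simulate a BOLD series from band-power envelopes
#'
#' Realizes the linear delay-embedded model: each band envelope is z-scored,
#' then for every time point with a full 12-s history the BOLD value is
#' `sum_b sum_d coeffs[b, d] * env_z[b, t - d]` plus Gaussian noise scaled to
#' the requested signal-to-noise variance ratio. The first 47 points
#' (incomplete history) are dropped and the output is z-scored.
#'
#' @param envelopes Band-power matrix at 4 Hz (bands x time).
#' @param truth A [ground_truth()] whose `coeffs` rows match the envelopes.
#' @param snr Signal-to-noise variance ratio (`Inf` = noiseless).
#' @param seed Seed for the noise draw.
#' @return Numeric z-scored BOLD vector of length `ncol(envelopes) - 47` with
#'   a `noise_sd` attribute (the realized noise sd).
#' @export
simulate_bold <- function(envelopes, truth, snr = Inf, seed = 1L) {
  if (nrow(envelopes) != nrow(truth$coeffs)) {
    abort("band count mismatch between envelopes and ground truth.")
  }
  n4 <- ncol(envelopes)
  if (n4 < 48L) abort("envelopes must cover at least 12 s at 4 Hz.")
  envz <- zscore_rows(envelopes)
  y <- delay_embed_predict(envz, truth$coeffs)
  s <- sd(y)
  noise_sd <- if (is.finite(snr) && s > 0) s / sqrt(snr) else 0
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(y), sd = noise_sd))
  }
  if (sd(y) > 0) y <- as.numeric(scale(y))
  attr(y, "noise_sd") <- noise_sd
  y
}

# z-score each row; constant rows are left centered at zero.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- row_sds(m)
  s[s == 0] <- 1
  (m - mu) / s
}

# y[t] = sum_{b,d} coeffs[b, d+1] * bands[b, t - d] for t = 48..T.
delay_embed_predict <- function(bands, coeffs) {
  n4 <- ncol(bands)
  nd <- ncol(coeffs)
  y <- numeric(n4 - nd + 1L)
  for (d in 0:(nd - 1L)) {
    y <- y + as.numeric(coeffs[, d + 1L] %*% bands[, (nd - d):(n4 - d), drop = FALSE])
  }
  y
}

#' Simulate a full multi-session study with known ground truth
#'
#' The first `n_positive` sessions share one smooth random coefficient matrix;
#' the remaining sessions get independently perturbed copies (perturbation
#' scale `outlier_perturbation`, renormalized to equal Frobenius norm).
#' Session band powers are the generator's own normalized envelopes, so the
#' true mapping is known exactly at model resolution.
#'
#' @param spec A [sim_spec()].
#' @param scheme Band scheme; defaults to ten uniform bands over 1-41 Hz.
#' @return A list with `sessions` (list of [session_dataset()]), `truths`
#'   (list of [ground_truth()]), `labels` (character, "positive"/"outlier"),
#'   `scheme` and `spec`.
#' @export
simulate_study <- function(spec, scheme = uniform_scheme()) {
  nb <- n_bands(scheme)
  base <- with_seed(derive_seed(spec$seed, 0L), smooth_coeffs(nb, 48L))
  n4 <- round(spec$duration_s * 4)
  sessions <- vector("list", spec$n_sessions)
  truths <- vector("list", spec$n_sessions)
  labels <- rep(c("positive", "outlier"),
                c(spec$n_positive, spec$n_sessions - spec$n_positive))
  for (i in seq_len(spec$n_sessions)) {
    seed_i <- derive_seed(spec$seed, i)
    if (labels[i] == "positive") {
      co <- base
    } else {
      co <- with_seed(derive_seed(seed_i, 13L), {
        p <- base + spec$outlier_perturbation * matrix(rnorm(nb * 48L), nb, 48L)
        p * sqrt(sum(base^2) / sum(p^2))
      })
    }
    env <- sim_envelopes(nb, n4, seed_i)
    bold <- simulate_bold(env, ground_truth(co, scheme), snr = spec$snr,
                          seed = derive_seed(seed_i, 2L))
    truths[[i]] <- ground_truth(co, scheme, noise_sd = attr(bold, "noise_sd"),
                                session_group = labels[i])
    sessions[[i]] <- session_dataset(zscore_rows(env), as.numeric(bold), scheme,
                                     subject_id = sprintf("sub%02d", i),
                                     session_id = sprintf("s%02d", i))
  }
  list(sessions = sessions, truths = truths, labels = labels,
       scheme = scheme, spec = spec)
}

# Smooth random coefficient matrix (unit Frobenius norm): Gaussian entries
# smoothed along the delay axis so fingerprints resemble slow hemodynamics.
smooth_coeffs <- function(nb, nd) {
  m <- matrix(rnorm(nb * nd), nb, nd)
  k <- exp(-0.5 * ((-6:6) / 2)^2)
  k <- k / sum(k)
  m <- t(apply(m, 1L, function(r) {
    as.numeric(stats::filter(c(rev(r[1:6]), r, rev(r[(nd - 5):nd])), k,
                             sides = 2))[7:(nd + 6)]
  }))
  m / sqrt(sum(m^2))
}
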