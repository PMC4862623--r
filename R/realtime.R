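#' Initialize the streaming neurofeedback engine
#'
#' The engine keeps a rolling buffer of notch-filtered raw EEG (15 s: the
#' 12-s multiplication window, 1-s analysis-edge margins, and one 3-s
#' packet), carries the notch filter state across packets so the streamed
#' filter output is sample-identical to a batch filter of the whole record,
#' and emits one predicted BOLD (cEFP) value per packet once enough history
#' exists.
#'
#' @param model The [efp_model()] driving the prediction.
#' @param ref A [rest_reference()] from [rest_calibration()].
#' @param rate_hz Raw EEG sampling rate.
#' @param packet_s Packet duration in seconds (default 3, the fMRI TR).
#' @param capacity_s Buffer capacity in seconds.
#' @param line_hz Notch frequency (`NULL` disables the notch).
#' @param support_s Stockwell window half-support (and edge margin), seconds.
#' @return An object of class `stream_state`.
#' @export
stream_init <- function(model, ref, rate_hz = 250, packet_s = 3,
                        capacity_s = 15, line_hz = 50, support_s = 1) {
  if (is.null(ref)) abort("a rest reference is required before streaming.")
  if (length(ref$mean_per_band) != nrow(model$coeffs)) {
    abort("rest reference band count does not match the model.")
  }
  structure(list(
    model = model, ref = ref, rate_hz = rate_hz, packet_s = packet_s,
    capacity_s = capacity_s, line_hz = line_hz, support_s = support_s,
    notch = if (is.null(line_hz)) NULL else notch_coefficients(line_hz, rate_hz),
    notch_state = c(0, 0), buffer = numeric(0), t_s = 0,
    emitted = tibble(packet = integer(0), t_s = numeric(0), value = numeric(0))
  ), class = "stream_state")
}

#' Push one EEG packet and emit the next cEFP value
#'
#' The packet is notch-filtered (stateful), appended to the buffer (oldest
#' samples dropped beyond capacity) and the full preprocessing chain
#' (Stockwell -> band collapse -> 4 Hz block means -> rest-reference
#' normalization) is applied to the buffer. The last 48 non-edge 4 Hz columns
#' are multiplied element-wise by the fingerprint coefficients and summed
#' (plus intercept). Until enough history exists the emission is
#' `warming_up` (`NA`).
#'
#' @param state A `stream_state`.
#' @param packet Numeric vector of exactly `packet_s * rate_hz` samples.
#' @return List with `state` (updated) and `value` (emitted cEFP value, or
#'   `NA` while warming up). The emitted value predicts BOLD at absolute time
#'   `state$t_s - support_s` (a fixed reporting latency of one edge margin).
#' @export
push_packet <- function(state, packet) {
  n_exp <- round(state$packet_s * state$rate_hz)
  if (length(packet) != n_exp) {
    abort(sprintf("packet must hold exactly %d samples.", n_exp))
  }
  if (!is.null(state$notch)) {
    f <- notch_apply(packet, state$notch, state$notch_state)
    packet <- f$y
    state$notch_state <- f$state
  }
  buf <- c(state$buffer, packet)
  cap <- round(state$capacity_s * state$rate_hz)
  if (length(buf) > cap) buf <- buf[(length(buf) - cap + 1L):length(buf)]
  state$buffer <- buf
  state$t_s <- state$t_s + state$packet_s
  need_s <- 12 + 2 * state$support_s
  if (length(buf) / state$rate_hz < need_s) {
    return(list(state = state, value = NA_real_))
  }
  bp <- stream_features(state)
  win <- bp$values[, ncol(bp$values):(ncol(bp$values) - 47L), drop = FALSE]
  # win column d+1 is the band power at delay d (newest column first),
  # matching the delay-ascending coefficient layout
  value <- sum(win * state$model$coeffs) + state$model$intercept
  t_emit <- bp$times_s[length(bp$times_s)]
  state$emitted <- dplyr::bind_rows(
    state$emitted,
    tibble(packet = as.integer(round(state$t_s / state$packet_s)),
           t_s = t_emit, value = value))
  list(state = state, value = value)
}

# Featurize the current buffer: Stockwell with the truncated window, collapse
# to the model's bands, 4 Hz block means, edge-column exclusion, reference
# normalization. Times are absolute seconds from stream start.
stream_features <- function(state) {
  buf_rec <- eeg_recording(state$buffer, state$rate_hz)
  bp <- featurize_recording(buf_rec, state$model$scheme, ref = state$ref,
                            line_hz = NULL, support_s = state$support_s,
                            edge_exclude_s = state$support_s)
  bp$times_s <- bp$times_s + (state$t_s - length(state$buffer) / state$rate_hz)
  bp
}

#' Calibrate the rest reference and rest-period feedback statistics
#'
#' Featurizes a rest recording (raw scale), takes per-band mean and sd as the
#' normalization reference, then runs the model over the normalized rest
#' features to obtain the participant's rest-period cEFP mean and standard
#' deviation for the feedback mapper.
#'
#' @param rest_rec An [eeg_recording()] of at least 60 s.
#' @param model The [efp_model()] that will generate feedback.
#' @param line_hz,support_s As in [stream_init()].
#' @return List with `ref` ([rest_reference()]), `rest_mean`, `rest_sd` and
#'   the rest-period cEFP `values`.
#' @export
rest_calibration <- function(rest_rec, model, line_hz = 50, support_s = 1) {
  if (nrow(rest_rec$samples) / rest_rec$rate_hz < 60) {
    abort("rest recording must be at least 60 s.")
  }
  raw <- featurize_recording(rest_rec, model$scheme, ref = NULL,
                             line_hz = line_hz, support_s = support_s,
                             edge_exclude_s = support_s)
  sds <- row_sds(raw$values)
  if (any(sds < 1e-12)) abort("degenerate rest data: a band has (near-)zero variance.")
  ref <- rest_reference(rowMeans(raw$values), sds,
                        source_session = rest_rec$session_id)
  normed <- normalize_bands(raw, ref)
  vals <- predict_bands(model, normed$values, times_s = normed$times_s)
  if (sd(vals) == 0) abort("degenerate rest cEFP series (zero variance).")
  list(ref = ref, rest_mean = mean(vals), rest_sd = sd(vals),
       values = as.numeric(vals))
}

#' Feedback-volume mapping state
#'
#' Maps cEFP values to auditory loudness: 50 dB at the rest mean, +-10 dB per
#' standard deviation, clipped to `[10, 90]` dB. The scaling sd is reset
#' after each neurofeedback period from the values recorded during it.
#'
#' @param rest_mean Rest-period cEFP mean.
#' @param rest_sd Rest-period cEFP standard deviation (> 0).
#' @return An object of class `feedback_state`.
#' @export
feedback_state <- function(rest_mean, rest_sd) {
  stopifnot_scalar_num(rest_sd, "rest_sd", positive = TRUE)
  structure(list(rest_mean = rest_mean, current_sd = rest_sd,
                 db_min = 10, db_mid = 50, db_max = 90, db_per_sd = 10,
                 period_values = numeric(0)),
            class = "feedback_state")
}

#' Map a cEFP value to feedback loudness
#'
#' @param fb A [feedback_state()].
#' @param value Current cEFP value (accumulated for the period-end sd reset).
#' @return List with `state` (updated) and `db` (loudness in dB).
#' @export
map_to_db <- function(fb, value) {
  db <- fb$db_mid + fb$db_per_sd * (value - fb$rest_mean) / fb$current_sd
  db <- min(fb$db_max, max(fb$db_min, db))
  fb$period_values <- c(fb$period_values, value)
  list(state = fb, db = db)
}

#' Close a neurofeedback period and reset the feedback scaling
#'
#' Sets the scaling sd to the sample standard deviation of the values
#' recorded during the period and clears the accumulator; the rest mean is
#' unchanged. With fewer than two recorded values the state is returned
#' unchanged with a warning.
#'
#' @param fb A [feedback_state()].
#' @return The updated [feedback_state()].
#' @export
end_period <- function(fb) {
  if (length(fb$period_values) < 2L) {
    warn("fewer than 2 values in the period; feedback scaling unchanged.")
    return(fb)
  }
  fb$current_sd <- sd(fb$period_values)
  fb$period_values <- numeric(0)
  fb
}

#' Replay a recording through the streaming engine
#'
#' Cuts a recording into consecutive packets and pushes them through
#' [push_packet()], optionally mapping each emission to loudness.
#'
#' @param rec An [eeg_recording()].
#' @param model The [efp_model()].
#' @param ref A [rest_reference()].
#' @param fb Optional [feedback_state()] for loudness logging.
#' @param ... Passed to [stream_init()].
#' @return Tibble log: `packet`, `t_s`, `value` (`NA` while warming up) and,
#'   with `fb`, `loudness_db`.
#' @export
stream_replay <- function(rec, model, ref, fb = NULL, ...) {
  x <- get_channel(rec)
  st <- stream_init(model, ref, rate_hz = rec$rate_hz, ...)
  np <- floor(length(x) / (st$packet_s * st$rate_hz))
  logs <- vector("list", np)
  for (p in seq_len(np)) {
    idx <- ((p - 1L) * st$packet_s * st$rate_hz + 1L):(p * st$packet_s * st$rate_hz)
    res <- push_packet(st, x[idx])
    st <- res$state
    row <- tibble(packet = p,
                  t_s = if (is.na(res$value)) NA_real_ else
                    st$emitted$t_s[nrow(st$emitted)],
                  value = res$value)
    if (!is.null(fb) && !is.na(res$value)) {
      m <- map_to_db(fb, res$value)
      fb <- m$state
      row$loudness_db <- m$db
    } else if (!is.null(fb)) {
      row$loudness_db <- NA_real_
    }
    logs[[p]] <- row
  }
  out <- dplyr::bind_rows(logs)
  attr(out, "state") <- st
  attr(out, "feedback") <- fb
  out
}
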