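#' Validation benchmarks
#'
#' Self-contained reproducibility checks that exercise the whole pipeline on
#' synthetic data with known ground truth. Each returns a small list of
#' measured quantities; `scripts/acceptance.R` and the test suite run them.
#'
#' @name benchmarks
NULL

#' Ridge solver against a dense normal-equation solve
#'
#' Draws random (X, y, lambda) instances and compares [ridge_fit()] with a
#' direct `solve(Xc'Xc + lambda I, Xc'yc)` on the centered data.
#'
#' @param n_instances Number of random instances.
#' @param seed RNG seed.
#' @return List with `max_diff` (largest absolute weight/intercept
#'   discrepancy) and `n`.
#' @export
benchmark_ridge_oracle <- function(n_instances = 100L, seed = 1L) {
  diffs <- with_seed(seed, {
    vapply(seq_len(n_instances), function(i) {
      n <- sample(30:80, 1)
      p <- sample(3:12, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      lam <- 10^stats::runif(1, -2, 2)
      fit <- ridge_fit(X, y, lam)
      Xc <- scale(X, scale = FALSE)
      yc <- y - mean(y)
      w <- solve(crossprod(Xc) + lam * diag(p), crossprod(Xc, yc))
      b <- mean(y) - sum(colMeans(X) * w)
      max(abs(c(fit$weights - w, fit$intercept - b)))
    }, numeric(1))
  })
  list(max_diff = max(diffs), n = n_instances)
}

#' Parameter recovery on synthetic sessions
#'
#' Fits individual fingerprints on seeded synthetic sessions (default 300 s,
#' snr 10) and measures (a) the Pearson correlation between fitted and
#' planted coefficient matrices and (b) the prediction correlation on a
#' held-out final segment of each session, with the model refit on the
#' remaining initial segment.
#'
#' @param n_sessions Number of seeded sessions.
#' @param duration_s,snr Session conditions.
#' @param holdout_fraction Final fraction of each session held out.
#' @param cfg A [cv_config()].
#' @param seed RNG seed.
#' @return List with `median_coeff_r`, `median_heldout_r`, per-session
#'   tibble `detail`, and `n`.
#' @export
benchmark_parameter_recovery <- function(n_sessions = 10L, duration_s = 300,
                                         snr = 10, holdout_fraction = 0.2,
                                         cfg = cv_config(), seed = 1L) {
  detail <- purrr::map_dfr(seq_len(n_sessions), function(i) {
    spec <- sim_spec(n_sessions = 1L, n_positive = 1L, duration_s = duration_s,
                     seed = derive_seed(seed, i), snr = snr)
    st <- simulate_study(spec)
    ds <- st$sessions[[1]]
    truth <- st$truths[[1]]
    model <- fit_individual_efp(ds, cfg)
    coeff_r <- cor(as.numeric(model$coeffs), as.numeric(truth$coeffs))
    n4 <- ncol(ds$bands)
    cut <- floor(n4 * (1 - holdout_fraction))
    train <- session_dataset(ds$bands[, 1:cut, drop = FALSE],
                             as.numeric(scale(ds$bold[1:(cut - 47L)])),
                             ds$scheme, ds$subject_id, ds$session_id)
    m2 <- fit_individual_efp(train, cfg)
    tail_bands <- ds$bands[, (cut - 47L + 1L):n4, drop = FALSE]
    yhat <- predict_bands(m2, tail_bands)
    ytail <- ds$bold[(cut - 47L + 1L):(n4 - 47L)]
    tibble(session = i, coeff_r = coeff_r,
           heldout_r = cor(as.numeric(yhat), ytail))
  })
  list(median_coeff_r = stats::median(detail$coeff_r),
       median_heldout_r = stats::median(detail$heldout_r),
       detail = detail, n = n_sessions)
}

#' One-class selection recovery across seeded studies
#'
#' Simulates studies with planted positive and outlier sessions, fits an
#' individual fingerprint per session, clusters them and selects the
#' positive set, scoring how many planted positives are recovered. Also
#' reports the ratio of cross-group to within-group fingerprint distance.
#'
#' @param n_studies Number of seeded studies.
#' @param n_sessions,n_positive Study composition.
#' @param duration_s,snr,outlier_perturbation Study conditions.
#' @param cfg A [cv_config()] (a light one keeps the benchmark fast).
#' @param seed RNG seed.
#' @return List with `recovery_fraction` (share of studies recovering >= 9 of
#'   10 planted positives), `median_distance_ratio`, per-study `detail`, `n`.
#' @export
benchmark_oneclass_recovery <- function(n_studies = 20L, n_sessions = 15L,
                                        n_positive = 10L, duration_s = 180,
                                        snr = 10, outlier_perturbation = 1,
                                        cfg = cv_config(n_inner_splits = 10L,
                                                        lambda_grid = 10^seq(-1, 3, length.out = 7)),
                                        seed = 1L) {
  detail <- purrr::map_dfr(seq_len(n_studies), function(s) {
    spec <- sim_spec(n_sessions = n_sessions, n_positive = n_positive,
                     duration_s = duration_s, seed = derive_seed(seed, s),
                     snr = snr, outlier_perturbation = outlier_perturbation)
    st <- simulate_study(spec)
    models <- lapply(st$sessions, fit_individual_efp, cfg = cfg)
    vecs <- lapply(models, rebin_efp, uniform_scheme = st$scheme)
    names(vecs) <- vapply(st$sessions, function(d) d$session_id, character(1))
    dm <- pairwise_efp_distances(vecs)
    pos <- which(st$labels == "positive")
    within <- dm[pos, pos][upper.tri(diag(length(pos)))]
    cross <- dm[pos, -pos]
    sel <- oneclass_select(models, st$scheme, n_select = n_positive)
    planted <- vapply(st$sessions[pos], function(d) d$session_id, character(1))
    tibble(study = s, n_recovered = sum(sel$selected %in% planted),
           distance_ratio = stats::median(cross) / stats::median(within))
  })
  list(recovery_fraction = mean(detail$n_recovered >= 9L),
       median_distance_ratio = stats::median(detail$distance_ratio),
       detail = detail, n = n_studies)
}

#' Common-model benefit over single-session models
#'
#' Over seeded replicates: fit a common model on k positive training
#' sessions and one individual model on a single positive session, then
#' compare their mean prediction correlation on fresh positive-group test
#' sessions. Returns the one-sided sign-test p value for "the common model
#' wins".
#'
#' @param n_reps Number of replicates.
#' @param k_train Positive training sessions per replicate.
#' @param n_test_sessions Fresh positive test sessions per replicate.
#' @param duration_s,snr Session conditions.
#' @param cfg A light [cv_config()].
#' @param seed RNG seed.
#' @return List with `mean_cefp_r`, `mean_efp_r`, `wins`, `sign_test_p`,
#'   per-replicate `detail`, `n`.
#' @export
benchmark_cefp_gain <- function(n_reps = 20L, k_train = 5L,
                                n_test_sessions = 5L, duration_s = 120,
                                snr = 1,
                                cfg = cv_config(n_inner_splits = 6L,
                                                lambda_grid = 10^seq(-1, 3, length.out = 7)),
                                seed = 1L) {
  detail <- purrr::map_dfr(seq_len(n_reps), function(rep) {
    spec <- sim_spec(n_sessions = k_train + n_test_sessions,
                     n_positive = k_train + n_test_sessions,
                     duration_s = duration_s, seed = derive_seed(seed, rep),
                     snr = snr)
    st <- simulate_study(spec)
    train <- st$sessions[seq_len(k_train)]
    test <- st$sessions[(k_train + 1L):(k_train + n_test_sessions)]
    cefp <- fit_cefp(train, cfg)
    efp <- fit_individual_efp(train[[1]], cfg)
    tibble(rep = rep,
           cefp_r = mean(cross_apply(cefp$model, test)$r),
           efp_r = mean(cross_apply(efp, test)$r))
  })
  wins <- sum(detail$cefp_r > detail$efp_r)
  list(mean_cefp_r = mean(detail$cefp_r), mean_efp_r = mean(detail$efp_r),
       wins = wins,
       sign_test_p = stats::pbinom(wins - 1L, n_reps, 0.5, lower.tail = FALSE),
       detail = detail, n = n_reps)
}

#' Streaming versus batch prediction equivalence
#'
#' Simulates a raw EEG session, featurizes and predicts it offline in one
#' pass, then replays the same samples packet-by-packet through the
#' streaming engine, and reports the largest absolute difference between
#' streamed emissions and offline predictions at common (non-edge) time
#' points.
#'
#' @param duration_s Session length in seconds.
#' @param rate_hz Raw EEG rate.
#' @param seed RNG seed.
#' @return List with `max_diff`, `n_common` (compared time points), `n`.
#' @export
benchmark_stream_equivalence <- function(duration_s = 120, rate_hz = 250,
                                         seed = 1L) {
  spec <- sim_spec(n_sessions = 1L, n_positive = 1L, duration_s = duration_s,
                   eeg_rate_hz = rate_hz, seed = seed)
  rec <- simulate_eeg(spec, 1L)
  scheme <- attr(rec, "scheme")
  model <- with_seed(derive_seed(seed, 99L),
                     efp_model(smooth_coeffs(n_bands(scheme), 48L),
                               intercept = 0.1, scheme = scheme, lambda = 1))
  # reference statistics from the first 60 s, as a rest block
  rest <- eeg_recording(get_channel(rec)[seq_len(60 * rate_hz)], rate_hz)
  cal <- rest_calibration(rest, model)
  filt <- notch_filter(rec, 50)
  bp <- featurize_recording(filt, scheme, ref = cal$ref, line_hz = NULL)
  offline <- predict_bands(model, bp$values, times_s = bp$times_s)
  off_t <- round(attr(offline, "times") * 4)
  log <- stream_replay(rec, model, cal$ref)
  emitted <- log[!is.na(log$value), ]
  common <- match(round(emitted$t_s * 4), off_t)
  ok <- !is.na(common)
  list(max_diff = max(abs(emitted$value[ok] - offline[common[ok]])),
       n_common = sum(ok), n = duration_s)
}

#' Equal-area banding quality on simulated spectra
#'
#' Draws random smooth 1/f-like spectra with peaks, bands each with
#' [equal_area_bands()], and measures the worst deviation of any band's area
#' from the ideal equal share, in units of the largest single 1 Hz bin area.
#'
#' @param n_spectra Number of random spectra.
#' @param seed RNG seed.
#' @return List with `max_dev_bins` (worst deviation over all spectra, in
#'   largest-bin units), `flat_exact` (TRUE if a flat spectrum yields exact
#'   4 Hz bands), `n`.
#' @export
benchmark_equal_area <- function(n_spectra = 20L, seed = 1L) {
  devs <- with_seed(seed, {
    vapply(seq_len(n_spectra), function(i) {
      f <- 1:40
      s <- 1 / f^stats::runif(1, 0.5, 1.5) +
        stats::runif(1, 0.2, 2) * exp(-0.5 * ((f - stats::runif(1, 5, 15)) / 2)^2)
      sc <- equal_area_bands(s, 10L)
      areas <- vapply(seq_len(10L), function(b) {
        sum(s[f >= sc$edges_hz[b] & f < sc$edges_hz[b + 1L]])
      }, numeric(1))
      max(abs(areas - sum(s) / 10)) / max(s)
    }, numeric(1))
  })
  flat <- equal_area_bands(rep(1, 40), 10L)
  list(max_dev_bins = max(devs),
       flat_exact = isTRUE(all.equal(flat$edges_hz, seq(1, 41, by = 4))),
       n = n_spectra)
}
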