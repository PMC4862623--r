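# Small in-code fixtures shared across test files.

# Quick session with known truth: returns list(ds, truth, scheme).
quick_session <- function(duration_s = 100, snr = 10, seed = 1) {
  spec <- sim_spec(n_sessions = 1, n_positive = 1, duration_s = duration_s,
                   seed = seed, snr = snr)
  st <- simulate_study(spec)
  list(ds = st$sessions[[1]], truth = st$truths[[1]], scheme = st$scheme)
}

# Light CV configuration for fast fits in tests.
light_cfg <- function(seed = 1) {
  cv_config(n_inner_splits = 6L, lambda_grid = 10^seq(-1, 3, length.out = 7),
            seed = seed)
}

# Hand-built EFP model with given coefficients.
toy_model <- function(coeffs, scheme = uniform_scheme(), intercept = 0,
                      session_id = "toy") {
  efp_model(coeffs, intercept = intercept, scheme = scheme,
            fit_meta = list(session_id = session_id))
}
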