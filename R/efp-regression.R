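#' Cross-validation configuration
#'
#' Settings for the inner (model-selection) cross-validation: repeated random
#' block splits into 80/20 inner-training and validation sets, with the
#' validation set a contiguous temporal window (respecting autocorrelation),
#' and a log-spaced ridge penalty grid.
#'
#' @param n_inner_splits Number of random block splits (default 30).
#' @param validation_fraction Fraction of rows held out per split.
#' @param lambda_grid Positive penalty values; default 25 log-spaced values in
#'   `[1e-2, 1e4]`.
#' @param seed Seed for the split draws.
#' @param block_length_s Optional explicit validation-block length in seconds;
#'   by default the block length follows `validation_fraction`.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_inner_splits = 30L, validation_fraction = 0.2,
                      lambda_grid = 10^seq(-2, 4, length.out = 25),
                      seed = 1L, block_length_s = NULL) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must be in (0, 1).")
  }
  if (length(lambda_grid) == 0L || any(lambda_grid < 0)) {
    abort("`lambda_grid` must be non-empty and non-negative.")
  }
  structure(list(n_inner_splits = as.integer(n_inner_splits),
                 validation_fraction = validation_fraction,
                 lambda_grid = sort(as.numeric(lambda_grid)),
                 seed = as.integer(seed), block_length_s = block_length_s),
            class = "cv_config")
}

#' Build the delay-embedded design matrix of a session
#'
#' One row per BOLD time point with a full 12-s EEG history. Row `i`
#' concatenates, band-major with delay ascending, the band powers
#' `bands[b, t - d]` for delays `d = 0, 0.25, ..., 11.75 s` (48 columns per
#' band, 480 columns for 10 bands).
#'
#' @param ds A [session_dataset()].
#' @return List with `X` (matrix), `y` (BOLD vector) and `times` (4 Hz time
#'   indices of the rows, in seconds from the session's first band column).
#' @export
build_design_matrix <- function(ds) {
  X <- design_from_bands(ds$bands)
  list(X = X, y = ds$bold, times = attr(X, "times"))
}

# Delay embedding of an arbitrary bands x time matrix (48 delays at 4 Hz).
design_from_bands <- function(bands, n_delays = 48L, times_s = NULL) {
  n4 <- ncol(bands)
  nb <- nrow(bands)
  if (n4 < n_delays) abort("session too short for one 12-s delay window.")
  nr <- n4 - n_delays + 1L
  X <- matrix(0, nrow = nr, ncol = nb * n_delays)
  for (b in seq_len(nb)) {
    for (d in 0:(n_delays - 1L)) {
      X[, (b - 1L) * n_delays + d + 1L] <- bands[b, (n_delays - d):(n4 - d)]
    }
  }
  if (is.null(times_s)) times_s <- (seq_len(n4) - 1L) / 4
  attr(X, "times") <- times_s[n_delays:n4]
  X
}

#' Ridge regression fit
#'
#' Solves `(Xc' Xc + lambda I) w = Xc' yc` on column-centered data via an
#' eigendecomposition of the centered Gram matrix; the intercept restores the
#' means and is not penalized. With `lambda = 0` and a rank-deficient design
#' the minimum-norm (pseudo-inverse) solution is returned with a warning.
#'
#' @param X Design matrix (rows >= 2).
#' @param y Response vector.
#' @param lambda Non-negative penalty.
#' @return List with `weights` and `intercept`.
#' @export
ridge_fit <- function(X, y, lambda) {
  stopifnot_scalar_num(lambda, "lambda", nonneg = TRUE)
  if (nrow(X) < 2L) abort("need at least 2 rows.")
  sol <- ridge_solver(X, y)
  ridge_solve(sol, lambda)
}

# Precompute the centered Gram eigendecomposition once so a whole lambda grid
# can be solved cheaply. Accepts either a raw (X, y) pair or precomputed raw
# cross-products (used by the CV fast path).
ridge_solver <- function(X = NULL, y = NULL, G = NULL, s = NULL, xy = NULL,
                         ysum = NULL, n = NULL) {
  if (!is.null(X)) {
    G <- crossprod(X)
    s <- colSums(X)
    xy <- as.numeric(crossprod(X, y))
    ysum <- sum(y)
    n <- nrow(X)
  }
  m <- s / n
  ybar <- ysum / n
  Gc <- G - n * tcrossprod(m)
  q <- xy - n * m * ybar
  eg <- eigen(Gc, symmetric = TRUE)
  list(V = eg$vectors, d = pmax(eg$values, 0), vq = as.numeric(crossprod(eg$vectors, q)),
       m = m, ybar = ybar)
}

ridge_solve <- function(sol, lambda) {
  d <- sol$d
  if (lambda == 0) {
    tol <- max(d) * 1e-10
    keep <- d > tol
    if (!all(keep)) {
      warn("rank-deficient design with lambda = 0; returning the minimum-norm solution.")
    }
    coefv <- ifelse(keep, sol$vq / d, 0)
  } else {
    coefv <- sol$vq / (d + lambda)
  }
  w <- as.numeric(sol$V %*% coefv)
  list(weights = w, intercept = sol$ybar - sum(sol$m * w))
}

#' Normalized mean squared error
#'
#' Mean squared error divided by the (population) variance of the reference
#' series; predicting the mean gives exactly 1.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
nmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L) {
    abort("`y_true` and `y_pred` must be equal-length vectors (>= 2).")
  }
  v <- mean((y_true - mean(y_true))^2)
  if (v == 0) abort("`y_true` has zero variance; NMSE undefined.")
  mean((y_true - y_pred)^2) / v
}

#' Inner cross-validation for the ridge penalty
#'
#' Draws `n_inner_splits` seeded block splits. Each split holds out one
#' uniformly placed contiguous window of `validation_fraction` of the rows
#' (per session when `groups` is given, so validation blocks never span a
#' session boundary), fits every penalty in the grid on the remaining rows,
#' and scores validation NMSE. The penalty minimizing the mean validation
#' NMSE is selected; ties go to the larger penalty.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param cfg A [cv_config()].
#' @param times Optional row time stamps (carried through to the table).
#' @param groups Optional per-row session ids for concatenated sessions.
#' @return List with `lambda` (selected penalty) and `cv_table` (tibble:
#'   split, lambda, nmse).
#' @export
inner_cv_select <- function(X, y, cfg = cv_config(), times = NULL, groups = NULL) {
  n <- nrow(X)
  grid <- cfg$lambda_grid
  vf <- cfg$validation_fraction
  G <- crossprod(X)
  s <- colSums(X)
  xy <- as.numeric(crossprod(X, y))
  ysum <- sum(y)
  spans <- if (is.null(groups)) {
    list(seq_len(n))
  } else {
    lapply(split(seq_len(n), factor(groups, levels = unique(groups))), identity)
  }
  starts_max <- vapply(spans, function(ix) {
    len <- max(1, round(vf * length(ix)))
    length(ix) - len + 1
  }, numeric(1))
  if (any(starts_max < 1L)) abort("a session is too short for one validation block.")
  res <- with_seed(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$n_inner_splits), function(j) {
      val <- unlist(lapply(spans, function(ix) {
        len <- max(1L, round(vf * length(ix)))
        st <- sample.int(length(ix) - len + 1L, 1L)
        ix[st:(st + len - 1L)]
      }), use.names = FALSE)
      Xv <- X[val, , drop = FALSE]
      yv <- y[val]
      sol <- ridge_solver(G = G - crossprod(Xv), s = s - colSums(Xv),
                          xy = xy - as.numeric(crossprod(Xv, yv)),
                          ysum = ysum - sum(yv), n = n - length(val))
      err <- vapply(grid, function(l) {
        fit <- ridge_solve(sol, l)
        nmse(yv, as.numeric(Xv %*% fit$weights) + fit$intercept)
      }, numeric(1))
      tibble(split = j, lambda = grid, nmse = err)
    })
  })
  means <- res |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(nmse = mean(.data$nmse), .groups = "drop")
  best <- means$lambda[means$nmse <= min(means$nmse) + 1e-12]
  list(lambda = max(best), cv_table = res)
}

#' Fit an individual EFP model on one session
#'
#' Selects the ridge penalty by [inner_cv_select()] on the whole session, then
#' refits on all rows; the weight vector is reshaped to the (band x delay)
#' fingerprint matrix.
#'
#' @param ds A [session_dataset()].
#' @param cfg A [cv_config()].
#' @return An [efp_model()].
#' @export
fit_individual_efp <- function(ds, cfg = cv_config()) {
  dm <- build_design_matrix(ds)
  sel <- inner_cv_select(dm$X, dm$y, cfg, times = dm$times)
  fit <- ridge_fit(dm$X, dm$y, sel$lambda)
  efp_model(coeffs = matrix(fit$weights, nrow = nrow(ds$bands), byrow = TRUE),
            intercept = fit$intercept, scheme = ds$scheme, lambda = sel$lambda,
            fit_meta = list(subject_id = ds$subject_id,
                            session_id = ds$session_id,
                            n_rows = nrow(dm$X),
                            cv_splits = cfg$n_inner_splits))
}

#' Predict BOLD from band powers with a fitted model
#'
#' @param model An [efp_model()].
#' @param bands Bands x time matrix (normalized, 4 Hz).
#' @param times_s Optional column time stamps.
#' @return Numeric predictions with a `times` attribute.
#' @export
predict_bands <- function(model, bands, times_s = NULL) {
  if (nrow(bands) != nrow(model$coeffs)) abort("band count mismatch with model.")
  X <- design_from_bands(bands, ncol(model$coeffs), times_s)
  yhat <- as.numeric(X %*% as.vector(t(model$coeffs))) + model$intercept
  attr(yhat, "times") <- attr(X, "times")
  yhat
}

#' Prediction correlation of a model on a session
#'
#' Pearson r between predicted and observed BOLD over the session's valid
#' rows. A constant prediction (e.g. an all-zero model) is reported as r = 0
#' with a warning.
#'
#' @param model An [efp_model()].
#' @param ds A [session_dataset()].
#' @return Scalar correlation.
#' @export
evaluate_prediction <- function(model, ds) {
  yhat <- predict_bands(model, ds$bands)
  if (sd(yhat) == 0) {
    warn("constant prediction; reporting r = 0 by convention.")
    return(0)
  }
  cor(as.numeric(yhat), ds$bold)
}
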