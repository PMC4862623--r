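#' Band scheme for the common model
#'
#' Equal-area banding of the log-mean spectrum averaged across exactly the
#' selected positive sessions (distinct from the comparison scheme, which
#' averages across all sessions).
#'
#' @param spectra Numeric matrix of per-session log-mean 1 Hz spectra
#'   (sessions x frequency bins, e.g. rows from [log_mean_spectrum()]), or a
#'   single spectrum vector.
#' @param n_bands Number of bands.
#' @param freqs_hz Frequencies of the bins; defaults to `1:n_bins`.
#' @return A [band_scheme()].
#' @export
build_cefp_scheme <- function(spectra, n_bands = 10L, freqs_hz = NULL) {
  if (is.vector(spectra)) spectra <- matrix(spectra, nrow = 1L)
  if (nrow(spectra) < 1L) abort("need at least one spectrum.")
  equal_area_bands(colMeans(spectra), n_bands, freqs_hz)
}

#' Fit the common EFP by leave-one-session-out validation
#'
#' For each of the k positive sessions, the remaining k-1 sessions' design
#' rows are concatenated as one training unit; [inner_cv_select()] picks the
#' penalty with validation blocks drawn within sessions (never spanning a
#' session boundary); the fold model is evaluated on the held-out session.
#' The final model is refit on all k sessions with the penalty most often
#' selected across folds (ties toward more regularization).
#'
#' @param positive List of [session_dataset()]s featurized under one scheme.
#' @param cfg A [cv_config()].
#' @return An object of class `cefp_fit`: `model` (the [efp_model()]) and
#'   `loo` (tibble: fold, session_id, lambda, r, nmse).
#' @export
fit_cefp <- function(positive, cfg = cv_config()) {
  k <- length(positive)
  if (k < 3L) abort("need at least 3 positive sessions.")
  nbv <- vapply(positive, function(d) nrow(d$bands), integer(1))
  if (length(unique(nbv)) != 1L) abort("sessions must share one band scheme.")
  dms <- lapply(positive, build_design_matrix)
  ids <- vapply(positive, function(d) d$session_id, character(1))
  folds <- purrr::map_dfr(seq_len(k), function(j) {
    Xs <- lapply(dms[-j], function(d) d$X)
    X <- do.call(rbind, Xs)
    y <- unlist(lapply(dms[-j], function(d) d$y), use.names = FALSE)
    groups <- rep(ids[-j], vapply(Xs, nrow, integer(1)))
    if (var(y) == 0) {
      warn(sprintf("fold %d has a degenerate target; skipped.", j))
      return(tibble(fold = j, session_id = ids[j], lambda = NA_real_,
                    r = NA_real_, nmse = NA_real_))
    }
    sel <- inner_cv_select(X, y, cfg, groups = groups)
    fit <- ridge_fit(X, y, sel$lambda)
    mod <- efp_model(matrix(fit$weights, nrow = nbv[1], byrow = TRUE),
                     fit$intercept, positive[[j]]$scheme, sel$lambda)
    yhat <- predict_bands(mod, positive[[j]]$bands)
    tibble(fold = j, session_id = ids[j], lambda = sel$lambda,
           r = suppressWarnings(evaluate_prediction(mod, positive[[j]])),
           nmse = nmse(positive[[j]]$bold, as.numeric(yhat)))
  })
  lam_tab <- table(folds$lambda[!is.na(folds$lambda)])
  lam_best <- max(as.numeric(names(lam_tab)[lam_tab == max(lam_tab)]))
  X_all <- do.call(rbind, lapply(dms, function(d) d$X))
  y_all <- unlist(lapply(dms, function(d) d$y), use.names = FALSE)
  fit <- ridge_fit(X_all, y_all, lam_best)
  model <- efp_model(matrix(fit$weights, nrow = nbv[1], byrow = TRUE),
                     fit$intercept, positive[[1]]$scheme, lam_best,
                     fit_meta = list(session_id = "cEFP",
                                     training_sessions = ids,
                                     fold_lambdas = folds$lambda))
  structure(list(model = model, loo = folds), class = "cefp_fit")
}

#' @export
print.cefp_fit <- function(x, ...) {
  cat(sprintf("<cefp_fit> %d folds, lambda = %g, mean held-out r = %.3f\n",
              nrow(x$loo), x$model$lambda, mean(x$loo$r, na.rm = TRUE)))
  invisible(x)
}

#' One-row summary of a common-model fit
#'
#' @param x A `cefp_fit`.
#' @param ... Unused.
#' @return Tibble with fold count, final penalty, mean and sd of held-out r.
#' @method glance cefp_fit
#' @export
glance.cefp_fit <- function(x, ...) {
  tibble(k = nrow(x$loo), lambda = x$model$lambda,
         mean_r = mean(x$loo$r, na.rm = TRUE),
         sd_r = sd(x$loo$r, na.rm = TRUE),
         mean_nmse = mean(x$loo$nmse, na.rm = TRUE))
}

#' Per-fold held-out performance of a common-model fit
#'
#' @param x A `cefp_fit`.
#' @param ... Unused.
#' @return The LOO report tibble.
#' @method tidy cefp_fit
#' @export
tidy.cefp_fit <- function(x, ...) x$loo

#' Held-out prediction correlations as a dot plot
#'
#' @param object A `cefp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cefp_fit
#' @export
autoplot.cefp_fit <- function(object, ...) {
  ggplot2::ggplot(object$loo,
                  ggplot2::aes(x = .data$session_id, y = .data$r)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.6, linetype = 2) +
    ggplot2::labs(x = "held-out session", y = "prediction r",
                  title = "Leave-one-session-out validation of the common model")
}

#' Apply a model across sessions
#'
#' Evaluates prediction correlation per session and attaches a mean/sd
#' summary.
#'
#' @param model An [efp_model()].
#' @param sessions List of [session_dataset()]s.
#' @return Tibble with `session_id`, `subject_id`, `r`; summary in
#'   `attr(, "summary")`.
#' @export
cross_apply <- function(model, sessions) {
  out <- purrr::map_dfr(sessions, function(ds) {
    tibble(session_id = ds$session_id, subject_id = ds$subject_id,
           r = suppressWarnings(evaluate_prediction(model, ds)))
  })
  attr(out, "summary") <- c(mean = mean(out$r), sd = sd(out$r))
  out
}
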