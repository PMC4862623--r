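#' EEG fingerprint (EFP) model
#'
#' The fitted fingerprint: a (band x delay) coefficient matrix mapping the
#' last 12 s of banded EEG power (48 delays at 4 Hz) to a predicted ROI BOLD
#' value, plus its band scheme and ridge penalty.
#'
#' @param coeffs Numeric matrix (bands x 48 delays).
#' @param intercept Scalar intercept.
#' @param scheme The [band_scheme()] of the rows.
#' @param lambda Ridge penalty used in the fit.
#' @param fit_meta Optional provenance list.
#' @return An object of class `efp_model`.
#' @export
efp_model <- function(coeffs, intercept = 0, scheme = uniform_scheme(),
                      lambda = NA_real_, fit_meta = list()) {
  if (nrow(coeffs) != n_bands(scheme)) abort("coeffs rows must match band count.")
  if (ncol(coeffs) != 48L) abort("coeffs must have 48 delay columns (12 s at 4 Hz).")
  structure(list(coeffs = coeffs, intercept = intercept, scheme = scheme,
                 delay_grid_s = seq(0, by = 0.25, length.out = 48L),
                 lambda = lambda, fit_meta = fit_meta),
            class = "efp_model")
}

#' @export
print.efp_model <- function(x, ...) {
  cat(sprintf("<efp_model> %d bands x 48 delays, lambda = %s\n",
              nrow(x$coeffs),
              if (is.na(x$lambda)) "NA" else format(signif(x$lambda, 4))))
  if (!is.null(x$fit_meta$session_id) && nzchar(x$fit_meta$session_id %||% "")) {
    cat(sprintf(" fitted on %s/%s\n", x$fit_meta$subject_id %||% "",
                x$fit_meta$session_id))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy an EFP model into a long tibble
#'
#' @param x An [efp_model()].
#' @param ... Unused.
#' @return Tibble with `band`, `band_low_hz`, `band_high_hz`, `delay_s`,
#'   `weight`.
#' @method tidy efp_model
#' @export
tidy.efp_model <- function(x, ...) {
  e <- x$scheme$edges_hz
  nb <- nrow(x$coeffs)
  tidyr::expand_grid(band = seq_len(nb), delay_s = x$delay_grid_s) |>
    dplyr::mutate(band_low_hz = e[.data$band],
                  band_high_hz = e[.data$band + 1L],
                  weight = as.numeric(t(x$coeffs))) |>
    dplyr::select("band", "band_low_hz", "band_high_hz", "delay_s", "weight")
}

#' One-row summary of an EFP model
#'
#' @param x An [efp_model()].
#' @param ... Unused.
#' @return Tibble with band count, penalty, intercept and coefficient norm.
#' @method glance efp_model
#' @export
glance.efp_model <- function(x, ...) {
  tibble(n_bands = nrow(x$coeffs), n_delays = ncol(x$coeffs),
         lambda = x$lambda, intercept = x$intercept,
         coeff_norm = sqrt(sum(x$coeffs^2)))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Heatmap of an EFP coefficient matrix
#'
#' @param object An [efp_model()].
#' @param ... Unused.
#' @return A ggplot object (delay on x, band on y, weight as fill).
#' @method autoplot efp_model
#' @export
autoplot.efp_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_s, y = factor(.data$band),
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "delay (s)", y = "frequency band",
                  fill = "weight", title = "EEG fingerprint coefficients")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialize an EFP model to JSON
#'
#' Writes the coefficient matrix, band edges, delay grid, penalty and
#' provenance as a single JSON document.
#'
#' @param model An [efp_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_efp <- function(model, path) {
  obj <- list(coeffs = unclass(model$coeffs), intercept = model$intercept,
              band_edges_hz = model$scheme$edges_hz,
              delay_grid_s = model$delay_grid_s, lambda = model$lambda,
              fit_meta = model$fit_meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an EFP model from JSON
#'
#' @param path File written by [write_efp()].
#' @return An [efp_model()].
#' @export
read_efp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  efp_model(coeffs = as.matrix(obj$coeffs), intercept = obj$intercept,
            scheme = band_scheme(obj$band_edges_hz),
            lambda = obj$lambda %||% NA_real_,
            fit_meta = as.list(obj$fit_meta))
}
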