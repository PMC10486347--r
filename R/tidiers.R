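# broom-style tidiers for fitted calibration models.

#' Tidy a fitted calibration model
#'
#' For the PLS family, one row per retained wavelength with its regression
#' coefficient (standardized-variable scale). For LS-SVM, one row per
#' training sample with its dual coefficient. For the neural network, one
#' row per hidden unit with its output weight and input-weight norm.
#'
#' @param x A `carptex_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.carptex_model <- function(x, ...) {
  wl <- if (is.null(x$subset)) x$wavelengths else x$wavelengths[x$subset]
  switch(x$kind,
    plsr = , ipls = , sipls = , bipls = tibble::tibble(
      wavelength = wl, term = paste0("wl_", format(wl, trim = TRUE)),
      estimate = x$fit$beta
    ),
    lssvm = tibble::tibble(
      sample = seq_along(x$fit$alpha), term = "alpha",
      estimate = x$fit$alpha,
      bias = x$fit$b
    ),
    bpann = tibble::tibble(
      hidden_unit = seq_along(x$fit$w2), term = "output_weight",
      estimate = x$fit$w2,
      input_weight_norm = sqrt(colSums(x$fit$W1^2))
    )
  )
}

#' One-row summary of a fitted calibration model
#'
#' Reports the model kind, wavelength count, hyperparameters, and training
#' r_c / RMSEC (computed on the stored training fit).
#'
#' @param x A `carptex_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.carptex_model <- function(x, ...) {
  R <- model_factor_count(x)
  tibble::tibble(
    kind = x$kind,
    n_wl = if (is.null(x$subset)) length(x$wavelengths) else length(x$subset),
    factors = R,
    r_c = r_coefficient(x$y, x$fitted),
    rmsec = rmsec(x$y, x$fitted, R),
    n_obs = length(x$y)
  )
}
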