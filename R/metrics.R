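# Calibration/prediction accuracy metrics.

#' Root-mean-square error of calibration
#'
#' `RMSEC = sqrt( sum((y_ref - y_pred)^2) / (N - 1 - R) )`, where `R` is the
#' number of factors of the model (latent variables for the PLS family; by
#' package convention 2 effective hyperparameters for LS-SVM and 1 for the
#' neural network).
#'
#' @param y_ref Reference (measured) values.
#' @param y_pred Predicted values.
#' @param R Number of model factors.
#' @return Non-negative scalar.
#' @export
rmsec <- function(y_ref, y_pred, R) {
  stopifnot(length(y_ref) == length(y_pred))
  N <- length(y_ref)
  if (N <= R + 1) {
    stop("RMSEC undefined: need N > R + 1 (N = ", N, ", R = ", R, ")",
         call. = FALSE)
  }
  sqrt(sum((y_ref - y_pred)^2) / (N - 1 - R))
}

#' Root-mean-square error of prediction
#'
#' `RMSEP = sqrt( mean((y_ref - y_pred)^2) )`.
#'
#' @inheritParams rmsec
#' @return Non-negative scalar.
#' @export
rmsep <- function(y_ref, y_pred) {
  stopifnot(length(y_ref) == length(y_pred), length(y_ref) >= 1)
  sqrt(mean((y_ref - y_pred)^2))
}

#' Coefficient of determination between predicted and measured values
#'
#' Default mode is the squared Pearson correlation between predictions and
#' measurements, bounded in \[0, 1\] — the quantity whose calibration and
#' prediction flavours are reported as r_c and r_p. An alternative
#' `mode = "printed"` evaluates the residual-ratio form
#' `sum((yhat - y)^2) / sum((yhat - mean(y))^2)`; as published that ratio
#' approaches 0 (not 1) for a perfect model, so it is retained only for
#' transparency and is not the default.
#'
#' @param y_ref Measured values.
#' @param y_pred Predicted values.
#' @param mode "squared_pearson" (default) or "printed".
#' @return Scalar; in \[0, 1\] for the default mode.
#' @export
r_coefficient <- function(y_ref, y_pred, mode = c("squared_pearson", "printed")) {
  mode <- match.arg(mode)
  stopifnot(length(y_ref) == length(y_pred))
  if (stats::sd(y_ref) == 0 || stats::sd(y_pred) == 0) {
    stop("degenerate input: zero variance in y_ref or y_pred", call. = FALSE)
  }
  if (mode == "squared_pearson") {
    stats::cor(y_ref, y_pred)^2
  } else {
    sum((y_pred - y_ref)^2) / sum((y_pred - mean(y_ref))^2)
  }
}

# Factor count R entering the RMSEC denominator, per model kind.
model_factor_count <- function(model) {
  switch(model$kind,
    plsr = , ipls = , sipls = , bipls = model$hyperparams$ncomp,
    lssvm = 2L,
    bpann = 1L,
    1L
  )
}
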