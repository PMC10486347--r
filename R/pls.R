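# Univariate NIPALS partial least squares and the shared fit/predict contract.
#
# All six calibration models share one FittedModel surface (class
# `carptex_model`): X and y are standardized on the training set, the model
# function operates on standardized variables, and predict() inverse-scales
# back to the target's original units.

standardize_xy <- function(X, y) {
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  ym <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  list(xm = xm, xs = xs, ym = ym, ys = ys,
       Xs = sweep(sweep(X, 2, xm), 2, xs, "/"),
       ys_vec = (y - ym) / ys)
}

apply_x_scaling <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$xm), 2, scaling$xs, "/")
}

# NIPALS decomposition on already-standardized X, y. Returns the regression
# vector on standardized variables plus scores/loadings/weights.
nipals_pls <- function(Xs, ys, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  ncomp <- min(ncomp, n - 1, p)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xc <- Xs; yc <- ys
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p_a <- crossprod(Xc, t) / tt
    q_a <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(p_a)
    yc <- yc - q_a * t
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) {
    return(list(beta = rep(0, p), W = W[, 0, drop = FALSE],
                P = P[, 0, drop = FALSE], Tm = Tm[, 0, drop = FALSE],
                q = numeric(0), ncomp = 0L))
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  R <- W %*% solve(crossprod(P, W))
  beta <- as.vector(R %*% q)
  list(beta = beta, W = W, P = P, Tm = Tm, q = q, ncomp = a_used)
}

# Deterministic interleaved CV folds (no randomness).
cv_folds_idx <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L

# Choose the latent-variable count minimizing k-fold CV RMSE; ties -> fewer.
select_ncomp_cv <- function(X, y, max_ncomp, cv_folds = 5) {
  n <- nrow(X)
  k <- min(cv_folds, n)
  if (k < 2) stop("CV fold count must be at least 2", call. = FALSE)
  folds <- cv_folds_idx(n, k)
  max_ncomp <- max(1L, min(max_ncomp, n - ceiling(n / k) - 1L, ncol(X)))
  press <- numeric(max_ncomp)
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- standardize_xy(X[tr, , drop = FALSE], y[tr])
    fit <- nipals_pls(sc$Xs, sc$ys_vec, max_ncomp)
    Xte <- apply_x_scaling(X[!tr, , drop = FALSE], sc)
    # accumulate predictions per component count from the single fit
    if (fit$ncomp == 0L) {
      press <- press + sum((y[!tr] - sc$ym)^2)
      next
    }
    R <- fit$W %*% solve(crossprod(fit$P, fit$W))
    Tte <- Xte %*% R
    cum <- matrix(0, nrow(Xte), max_ncomp)
    acc <- rep(0, nrow(Xte))
    for (a in seq_len(max_ncomp)) {
      if (a <= fit$ncomp) acc <- acc + Tte[, a] * fit$q[a]
      cum[, a] <- acc
    }
    pred <- sc$ym + sc$ys * cum
    press <- press + colSums((y[!tr] - pred)^2)
  }
  which.min(round(press / n, 12))
}

new_carptex_model <- function(kind, fit, scaling, X, y, wavelengths,
                              subset = NULL, hyperparams = list(),
                              seed = NULL) {
  model <- structure(
    list(kind = kind, fit = fit, scaling = scaling,
         wavelengths = wavelengths, subset = subset,
         hyperparams = hyperparams, seed = seed,
         version = 1L),
    class = c(paste0("carptex_", kind), "carptex_model")
  )
  model$fitted <- predict(model, X)
  model$y <- y
  model
}

resolve_xy <- function(X, y) {
  if (inherits(X, "spectra_matrix")) {
    list(X = X$X, wavelengths = X$wavelengths)
  } else {
    list(X = as.matrix(X), wavelengths = seq_len(ncol(as.matrix(X))))
  }
}

#' Fit a full-spectrum PLSR model
#'
#' NIPALS partial least-squares regression of one texture indicator on the
#' (standardized) band reflectances. The latent-variable count can be fixed
#' or selected by deterministic k-fold cross-validation ("cv", the default),
#' minimizing CV RMSE.
#'
#' @param X `spectra_matrix` or numeric matrix (samples x bands).
#' @param y Numeric response, aligned with the rows of `X`.
#' @param ncomp Integer latent-variable count, or "cv".
#' @param cv_folds Folds for "cv" (default 5).
#' @param max_ncomp Search ceiling for "cv" (default 15).
#' @return A fitted model (class `carptex_model`).
#' @export
fit_plsr <- function(X, y, ncomp = "cv", cv_folds = 5, max_ncomp = 15) {
  rx <- resolve_xy(X, y)
  Xm <- rx$X
  if (length(y) != nrow(Xm)) stop("X and y are not aligned", call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate target: y is constant", call. = FALSE)
  if (identical(ncomp, "cv")) {
    ncomp <- select_ncomp_cv(Xm, y, max_ncomp, cv_folds)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(nrow(Xm) - 1, ncol(Xm))) {
    stop("ncomp must lie in [1, min(n_samples - 1, n_bands)]", call. = FALSE)
  }
  sc <- standardize_xy(Xm, y)
  fit <- nipals_pls(sc$Xs, sc$ys_vec, ncomp)
  new_carptex_model("plsr", fit, sc[c("xm", "xs", "ym", "ys")], Xm, y,
                    rx$wavelengths,
                    hyperparams = list(ncomp = fit$ncomp))
}

#' Predict from a fitted calibration model
#'
#' Applies the stored wavelength subset and training scaling, evaluates the
#' model function, and inverse-scales to the target's original units. Pure
#' function of (model, newdata).
#'
#' @param object A `carptex_model`.
#' @param newdata `spectra_matrix` or matrix on the model's full band grid
#'   (the subset is applied internally), or already-subset columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.carptex_model <- function(object, newdata, ...) {
  Xm <- if (inherits(newdata, "spectra_matrix")) newdata$X else as.matrix(newdata)
  full_p <- length(object$wavelengths)
  sub_p <- if (is.null(object$subset)) full_p else length(object$subset)
  if (ncol(Xm) == full_p) {
    if (!is.null(object$subset)) Xm <- Xm[, object$subset, drop = FALSE]
  } else if (ncol(Xm) != sub_p) {
    stop("grid consistency error: newdata has ", ncol(Xm),
         " bands; model expects ", full_p, " (full) or ", sub_p, " (subset)",
         call. = FALSE)
  }
  Xs <- apply_x_scaling(Xm, object$scaling)
  raw <- predict_core(object, Xs)
  as.vector(object$scaling$ym + object$scaling$ys * raw)
}

predict_core <- function(object, Xs) UseMethod("predict_core")

# Linear predictor evaluated row-wise via rowSums so each prediction is
# bitwise independent of how many rows are batched together (the pixel-wise
# map contract); BLAS %*% rounds differently for different batch shapes.
linear_predict <- function(Xs, beta) {
  rowSums(Xs * matrix(beta, nrow(Xs), ncol(Xs), byrow = TRUE))
}

#' @export
predict_core.carptex_plsr <- function(object, Xs) {
  linear_predict(Xs, object$fit$beta)
}

#' @export
print.carptex_model <- function(x, ...) {
  nw <- if (is.null(x$subset)) length(x$wavelengths) else length(x$subset)
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, function(v) paste(format(v, digits = 4),
                                                      collapse = "/"), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("<carptex_model> %s, %d wavelengths, %s\n", x$kind, nw, hp))
  invisible(x)
}
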