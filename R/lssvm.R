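# Least-squares support vector machine regression with an RBF kernel.
#
# Dual problem (Suykens form): with K_ij = exp(-||x_i - x_j||^2 / sigma2),
#   [ 0   1'            ] [ b     ]   [ 0 ]
#   [ 1   K + I/gamma   ] [ alpha ] = [ y ]
# solved here by block elimination through H = K + I/gamma:
#   b = (1' H^-1 y) / (1' H^-1 1),  alpha = H^-1 (y - b).
# The test suite checks this against a direct dense solve of the full
# (n+1) x (n+1) KKT system.

rbf_kernel <- function(X1, X2, sigma2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

solve_lssvm_dual <- function(K, y, gamma) {
  n <- length(y)
  H <- K + diag(n) / gamma
  sol <- tryCatch(solve(H, cbind(y, rep(1, n))),
                  error = function(e) NULL)
  if (is.null(sol)) {
    # jitter-and-retry once on a numerically singular system
    H <- H + diag(n) * 1e-10
    sol <- tryCatch(solve(H, cbind(y, rep(1, n))),
                    error = function(e) {
                      stop("LS-SVM solver error: singular dual system",
                           call. = FALSE)
                    })
  }
  eta <- sol[, 1]; nu <- sol[, 2]
  b <- sum(eta) / sum(nu)
  list(alpha = eta - nu * b, b = b)
}

#' Default hyperparameter grid for the LS-SVM search
#'
#' Log-spaced points spanning (1e-3, 1000] for both the regularization
#' parameter gamma and the RBF width sigma2.
#'
#' @param n Points per parameter (default 20).
#' @return Numeric vector.
#' @export
lssvm_grid <- function(n = 20) 10^seq(-3, 3, length.out = n)

#' Fit an LS-SVM regression model
#'
#' Solves the least-squares SVM dual exactly for fixed hyperparameters, or
#' picks (gamma, sigma2) minimizing deterministic k-fold CV RMSE over a
#' log-spaced grid in (1e-3, 1000] when either is "grid".
#'
#' @param X `spectra_matrix` or matrix.
#' @param y Response vector.
#' @param gamma Regularization parameter (> 0) or "grid".
#' @param sigma2 RBF kernel width (> 0) or "grid".
#' @param grid_points Points per parameter in grid mode (default 20).
#' @param cv_folds CV folds for grid mode (default 5).
#' @return Fitted `carptex_model` of kind "lssvm".
#' @export
fit_lssvm <- function(X, y, gamma = "grid", sigma2 = "grid",
                      grid_points = 20, cv_folds = 5) {
  rx <- resolve_xy(X, y)
  Xm <- rx$X
  if (length(y) != nrow(Xm)) stop("X and y are not aligned", call. = FALSE)
  sc <- standardize_xy(Xm, y)
  gammas <- if (identical(gamma, "grid")) lssvm_grid(grid_points) else as.numeric(gamma)
  sigma2s <- if (identical(sigma2, "grid")) lssvm_grid(grid_points) else as.numeric(sigma2)
  stopifnot(all(gammas > 0), all(sigma2s > 0))
  if (length(gammas) > 1 || length(sigma2s) > 1) {
    sel <- lssvm_cv_search(sc$Xs, sc$ys_vec, gammas, sigma2s, cv_folds)
    gamma <- sel$gamma; sigma2 <- sel$sigma2
  } else {
    gamma <- gammas; sigma2 <- sigma2s
  }
  K <- rbf_kernel(sc$Xs, sc$Xs, sigma2)
  dual <- solve_lssvm_dual(K, sc$ys_vec, gamma)
  fit <- list(alpha = dual$alpha, b = dual$b, support = sc$Xs, sigma2 = sigma2)
  new_carptex_model("lssvm", fit, sc[c("xm", "xs", "ym", "ys")], Xm, y,
                    rx$wavelengths,
                    hyperparams = list(gamma = gamma, sigma2 = sigma2))
}

# Grid search via per-(fold, sigma2) eigendecomposition of K, so each gamma
# costs only O(n^2).
lssvm_cv_search <- function(Xs, ys, gammas, sigma2s, cv_folds) {
  n <- nrow(Xs)
  k <- min(cv_folds, n)
  folds <- cv_folds_idx(n, k)
  err <- matrix(0, length(gammas), length(sigma2s))
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- Xs[tr, , drop = FALSE]; ytr <- ys[tr]
    Xte <- Xs[!tr, , drop = FALSE]; yte <- ys[!tr]
    ntr <- nrow(Xtr)
    for (js in seq_along(sigma2s)) {
      K <- rbf_kernel(Xtr, Xtr, sigma2s[js])
      eg <- eigen(K, symmetric = TRUE)
      Kte <- rbf_kernel(Xte, Xtr, sigma2s[js])
      Uy <- crossprod(eg$vectors, ytr)
      U1 <- crossprod(eg$vectors, rep(1, ntr))
      for (jg in seq_along(gammas)) {
        dinv <- 1 / (pmax(eg$values, 0) + 1 / gammas[jg])
        eta <- eg$vectors %*% (dinv * Uy)
        nu <- eg$vectors %*% (dinv * U1)
        b <- sum(eta) / sum(nu)
        alpha <- eta - nu * b
        pred <- Kte %*% alpha + b
        err[jg, js] <- err[jg, js] + sum((yte - pred)^2)
      }
    }
  }
  # ties -> smaller gamma, then smaller sigma2 (row-major scan order)
  best <- arrayInd(which.min(round(t(err), 12)), dim(t(err)))
  list(gamma = gammas[best[1, 2]], sigma2 = sigma2s[best[1, 1]],
       cv_sse = err)
}

#' @export
predict_core.carptex_lssvm <- function(object, Xs) {
  K <- rbf_kernel(Xs, object$fit$support, object$fit$sigma2)
  K %*% object$fit$alpha + object$fit$b
}
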