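# Single-hidden-layer backpropagation network (sigmoid hidden, linear output)
# trained full-batch with gradient descent plus momentum, following the study
# protocol: at most 1000 epochs, stop early when the MSE loss reaches the
# 1e-5 goal, learning rate and momentum factor both 0.01.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a backpropagation neural network regressor
#'
#' One hidden layer (default 10 sigmoid units), linear output, trained by
#' full-batch backpropagation with momentum on standardized X and y.
#' Deterministic given `seed`; the global RNG stream is left untouched.
#'
#' @param X `spectra_matrix` or matrix.
#' @param y Response vector.
#' @param hidden_size Hidden units (default 10).
#' @param seed Integer seed for weight initialization.
#' @param max_epochs Epoch cap (default 1000).
#' @param goal MSE stopping goal on standardized targets (default 1e-5).
#' @param lr Learning rate (default 0.01).
#' @param momentum Momentum factor (default 0.01).
#' @param init "uniform" (default; scaled uniform weights) or "zero".
#' @return Fitted `carptex_model` of kind "bpann"; `hyperparams` records the
#'   epochs run and final loss.
#' @export
fit_bpann <- function(X, y, hidden_size = 10, seed = 1, max_epochs = 1000,
                      goal = 1e-5, lr = 0.01, momentum = 0.01,
                      init = c("uniform", "zero")) {
  init <- match.arg(init)
  stopifnot(hidden_size >= 1, max_epochs >= 0, lr > 0, momentum >= 0)
  rx <- resolve_xy(X, y)
  Xm <- rx$X
  if (length(y) != nrow(Xm)) stop("X and y are not aligned", call. = FALSE)
  sc <- standardize_xy(Xm, y)
  Xs <- sc$Xs; ys <- sc$ys_vec
  n <- nrow(Xs); p <- ncol(Xs); h <- as.integer(hidden_size)
  weights <- with_seed(seed, {
    if (init == "zero") {
      list(W1 = matrix(0, p, h), b1 = rep(0, h), w2 = rep(0, h), b2 = 0)
    } else {
      # small fan-in-scaled hidden weights keep the sigmoids in their linear
      # range; a larger output layer speeds gradient flow under the fixed
      # learning rate
      list(W1 = matrix(stats::runif(p * h, -0.5, 0.5) / sqrt(p), p, h),
           b1 = stats::runif(h, -0.1, 0.1),
           w2 = stats::runif(h, -3, 3) / sqrt(h),
           b2 = 0)
    }
  })
  W1 <- weights$W1; b1 <- weights$b1; w2 <- weights$w2; b2 <- weights$b2
  vW1 <- W1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- 0
  forward <- function() {
    A1 <- sigmoid(sweep(Xs %*% W1, 2, b1, "+"))
    list(A1 = A1, yhat = as.vector(A1 %*% w2 + b2))
  }
  fw <- forward()
  loss <- mean((fw$yhat - ys)^2)
  epochs_run <- 0L
  trace <- loss
  while (epochs_run < max_epochs && loss > goal) {
    d_out <- 2 * (fw$yhat - ys) / n
    g_w2 <- as.vector(crossprod(fw$A1, d_out))
    g_b2 <- sum(d_out)
    d_A1 <- outer(d_out, w2)
    d_Z1 <- d_A1 * fw$A1 * (1 - fw$A1)
    g_W1 <- crossprod(Xs, d_Z1)
    g_b1 <- colSums(d_Z1)
    vW1 <- momentum * vW1 - lr * g_W1
    vb1 <- momentum * vb1 - lr * g_b1
    vw2 <- momentum * vw2 - lr * g_w2
    vb2 <- momentum * vb2 - lr * g_b2
    W1 <- W1 + vW1; b1 <- b1 + vb1; w2 <- w2 + vw2; b2 <- b2 + vb2
    fw <- forward()
    loss <- mean((fw$yhat - ys)^2)
    if (!is.finite(loss)) {
      stop("BP-ANN training diverged (loss not finite) at epoch ",
           epochs_run + 1L, call. = FALSE)
    }
    epochs_run <- epochs_run + 1L
    trace <- c(trace, loss)
  }
  fit <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  new_carptex_model("bpann", fit, sc[c("xm", "xs", "ym", "ys")], Xm, y,
                    rx$wavelengths,
                    hyperparams = list(hidden_size = h, epochs = epochs_run,
                                       final_loss = loss),
                    seed = seed)
}

#' @export
predict_core.carptex_bpann <- function(object, Xs) {
  A1 <- sigmoid(sweep(Xs %*% object$fit$W1, 2, object$fit$b1, "+"))
  as.vector(A1 %*% object$fit$w2 + object$fit$b2)
}
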