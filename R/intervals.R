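# Interval PLS family: iPLS, SiPLS, BiPLS.
#
# All three search equidistant contiguous band intervals with plain PLSR
# inside each candidate subset; the search criterion is the calibration
# RMSEC (N - 1 - R denominator, R = the candidate fit's latent count).

#' Split a band grid into equidistant contiguous intervals
#'
#' Sizes differ by at most one: the first `n_bands %% n_intervals` intervals
#' get the extra band.
#'
#' @param n_bands Total band count.
#' @param n_intervals Number of intervals (1..n_bands).
#' @return List of integer index vectors, disjoint and covering.
#' @export
make_intervals <- function(n_bands, n_intervals) {
  if (n_intervals < 1 || n_intervals > n_bands) {
    stop("n_intervals must lie in [1, n_bands]", call. = FALSE)
  }
  base <- n_bands %/% n_intervals
  extra <- n_bands %% n_intervals
  sizes <- rep(base, n_intervals) + c(rep(1, extra), rep(0, n_intervals - extra))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  purrr::map2(starts, ends, seq)
}

# Fit PLSR on a column subset and score it by training RMSEC.
fit_subset_plsr <- function(Xm, y, idx, ncomp, cv_folds) {
  Xsub <- Xm[, idx, drop = FALSE]
  nc <- if (identical(ncomp, "cv")) {
    select_ncomp_cv(Xsub, y, max_ncomp = min(15, length(idx)), cv_folds)
  } else {
    min(as.integer(ncomp), length(idx), nrow(Xsub) - 1L)
  }
  sc <- standardize_xy(Xsub, y)
  fit <- nipals_pls(sc$Xs, sc$ys_vec, nc)
  pred <- as.vector(sc$ym + sc$ys * (sc$Xs %*% fit$beta))
  list(fit = fit, scaling = sc[c("xm", "xs", "ym", "ys")],
       rmsec = rmsec(y, pred, fit$ncomp), ncomp = fit$ncomp)
}

finish_interval_model <- function(kind, cand, Xm, y, idx, wavelengths, extra) {
  model <- new_carptex_model(kind, cand$fit, cand$scaling,
                             Xm[, idx, drop = FALSE], y, wavelengths,
                             subset = sort(idx),
                             hyperparams = c(list(ncomp = cand$ncomp), extra))
  model
}

#' Interval PLS (single best interval)
#'
#' Splits the spectrum into equidistant intervals, fits a PLSR inside each,
#' and returns the model on the interval with the lowest RMSEC (ties broken
#' toward the lowest interval index).
#'
#' @param X `spectra_matrix` or matrix.
#' @param y Response vector.
#' @param n_intervals Number of intervals (default 10).
#' @param ncomp Latent count rule per interval: "cv" (default) or an integer
#'   (capped by the interval width).
#' @param cv_folds CV folds for "cv".
#' @return Fitted `carptex_model` of kind "ipls"; `hyperparams$interval`
#'   records the winner and `hyperparams$rmsec_by_interval` the search.
#' @export
fit_ipls <- function(X, y, n_intervals = 10, ncomp = "cv", cv_folds = 5) {
  rx <- resolve_xy(X, y)
  Xm <- rx$X
  intervals <- make_intervals(ncol(Xm), n_intervals)
  cands <- purrr::map(intervals, ~ fit_subset_plsr(Xm, y, .x, ncomp, cv_folds))
  scores <- vapply(cands, `[[`, 0, "rmsec")
  best <- which.min(scores) # which.min takes the first (lowest index) on ties
  finish_interval_model("ipls", cands[[best]], Xm, y, intervals[[best]],
                        rx$wavelengths,
                        list(interval = best, n_intervals = n_intervals,
                             rmsec_by_interval = scores))
}

#' @export
predict_core.carptex_ipls <- function(object, Xs) {
  linear_predict(Xs, object$fit$beta)
}

#' Synergy interval PLS (best interval combination)
#'
#' Exhaustive search over all combinations of `combo_size` intervals; a PLSR
#' is fitted on the concatenated bands of each combination and the one with
#' the lowest RMSEC wins.
#'
#' @inheritParams fit_ipls
#' @param combo_size Number of intervals per combination (default 2).
#' @param max_combos Budget cap on the number of combinations searched.
#' @return Fitted `carptex_model` of kind "sipls"; `hyperparams$combination`
#'   records the winning interval indices.
#' @export
fit_sipls <- function(X, y, n_intervals = 10, combo_size = 2, ncomp = "cv",
                      cv_folds = 5, max_combos = 10000) {
  if (combo_size > n_intervals) {
    stop("combo_size must not exceed n_intervals", call. = FALSE)
  }
  rx <- resolve_xy(X, y)
  Xm <- rx$X
  intervals <- make_intervals(ncol(Xm), n_intervals)
  combos <- utils::combn(n_intervals, combo_size, simplify = FALSE)
  if (length(combos) > max_combos) {
    stop("combinatorial budget exceeded (", length(combos), " > ", max_combos,
         "); reduce n_intervals or combo_size", call. = FALSE)
  }
  cands <- purrr::map(combos, function(cmb) {
    idx <- sort(unlist(intervals[cmb]))
    fit_subset_plsr(Xm, y, idx, ncomp, cv_folds)
  })
  scores <- vapply(cands, `[[`, 0, "rmsec")
  best <- which.min(scores)
  idx <- sort(unlist(intervals[combos[[best]]]))
  finish_interval_model("sipls", cands[[best]], Xm, y, idx, rx$wavelengths,
                        list(combination = combos[[best]],
                             n_intervals = n_intervals,
                             combo_size = combo_size))
}

#' @export
predict_core.carptex_sipls <- function(object, Xs) {
  linear_predict(Xs, object$fit$beta)
}

#' Backward interval PLS (interval elimination)
#'
#' Starting from all intervals, repeatedly drops the interval whose omission
#' yields the lowest RMSEC of the remainder, stopping when no drop improves
#' on the current RMSEC (or one interval remains). Returns the PLSR on the
#' surviving bands plus the elimination trace.
#'
#' @inheritParams fit_ipls
#' @return Fitted `carptex_model` of kind "bipls"; `hyperparams$survivors`
#'   and `hyperparams$trace` record the search.
#' @export
fit_bipls <- function(X, y, n_intervals = 10, ncomp = "cv", cv_folds = 5) {
  if (n_intervals < 2) stop("BiPLS needs n_intervals >= 2", call. = FALSE)
  rx <- resolve_xy(X, y)
  Xm <- rx$X
  intervals <- make_intervals(ncol(Xm), n_intervals)
  current <- seq_len(n_intervals)
  cur_cand <- fit_subset_plsr(Xm, y, sort(unlist(intervals[current])),
                              ncomp, cv_folds)
  trace <- integer(0)
  repeat {
    if (length(current) == 1) break
    drops <- purrr::map(seq_along(current), function(i) {
      keep <- current[-i]
      fit_subset_plsr(Xm, y, sort(unlist(intervals[keep])), ncomp, cv_folds)
    })
    scores <- vapply(drops, `[[`, 0, "rmsec")
    best <- which.min(scores)
    if (scores[best] < cur_cand$rmsec) {
      trace <- c(trace, current[best])
      current <- current[-best]
      cur_cand <- drops[[best]]
    } else break
  }
  idx <- sort(unlist(intervals[current]))
  finish_interval_model("bipls", cur_cand, Xm, y, idx, rx$wavelengths,
                        list(survivors = current, trace = trace,
                             n_intervals = n_intervals))
}

#' @export
predict_core.carptex_bipls <- function(object, Xs) {
  linear_predict(Xs, object$fit$beta)
}
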