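# Regression-coefficient (RC) wavelength selection.
#
# The beta-coefficient vector of a full-spectrum PLSR fit on standardized
# variables scores each band; bands where |beta| is large (globally, or at
# local peaks/valleys of the profile) are the optimal wavelengths.

#' Compute an RC profile from a full-spectrum PLSR fit
#'
#' @param X `spectra_matrix` or matrix.
#' @param y Indicator vector aligned with the rows of `X`.
#' @param ncomp Latent count for the underlying PLSR: "cv" (default,
#'   cross-validated as in [fit_plsr()]) or an integer.
#' @param cv_folds CV folds for "cv".
#' @return Object of class `rc_profile` with fields `beta` (standardized
#'   regression coefficients, one per band), `wavelengths`, `ncomp`.
#' @export
compute_rc_profile <- function(X, y, ncomp = "cv", cv_folds = 5) {
  model <- fit_plsr(X, y, ncomp = ncomp, cv_folds = cv_folds)
  structure(
    list(beta = model$fit$beta, wavelengths = model$wavelengths,
         ncomp = model$hyperparams$ncomp),
    class = "rc_profile"
  )
}

#' @export
print.rc_profile <- function(x, ...) {
  cat(sprintf("<rc_profile> %d bands, %d latent variables, max|beta| at %.1f nm\n",
              length(x$beta), x$ncomp, x$wavelengths[which.max(abs(x$beta))]))
  invisible(x)
}

#' Tidy an RC profile
#' @param x An `rc_profile`.
#' @param ... Unused.
#' @return Tibble with wavelength and beta columns.
#' @export
tidy.rc_profile <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths, beta = x$beta)
}

# Indices of local extrema of beta, treating plateaus as single extrema
# (leftmost index) and including the endpoints when they dominate their
# neighbour run.
local_extrema <- function(beta) {
  r <- rle(beta)
  v <- r$values
  starts <- cumsum(c(1, utils::head(r$lengths, -1)))
  m <- length(v)
  if (m == 1) return(1L)
  keep <- logical(m)
  for (i in seq_len(m)) {
    left <- if (i > 1) v[i - 1] else NA
    right <- if (i < m) v[i + 1] else NA
    is_max <- (is.na(left) || v[i] > left) && (is.na(right) || v[i] > right)
    is_min <- (is.na(left) || v[i] < left) && (is.na(right) || v[i] < right)
    keep[i] <- is_max || is_min
  }
  starts[keep]
}

#' Select optimal wavelengths from an RC profile
#'
#' Two modes: `top_k` takes the `param` bands of largest |beta| (ties broken
#' toward the lowest band index); `peak_threshold` keeps local peaks and
#' valleys of the beta profile whose |beta| exceeds `param * max(|beta|)`
#' (default param 0.1).
#'
#' @param profile An `rc_profile`.
#' @param mode "peak_threshold" (default) or "top_k".
#' @param param Threshold fraction in (0, 1) or k >= 1, per mode.
#' @return Object of class `wavelength_subset`: sorted band `indices`, their
#'   `wavelengths`, the `method`, and selection parameters.
#' @export
select_by_rc <- function(profile, mode = c("peak_threshold", "top_k"),
                         param = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "rc_profile"))
  beta <- profile$beta
  if (mode == "top_k") {
    k <- as.integer(param)
    if (k < 1 || k > length(beta)) {
      stop("top_k parameter must lie in [1, n_bands]", call. = FALSE)
    }
    ord <- order(-abs(beta), seq_along(beta))
    idx <- sort(ord[seq_len(k)])
  } else {
    if (param <= 0) stop("peak_threshold parameter must be > 0", call. = FALSE)
    cand <- local_extrema(beta)
    idx <- sort(cand[abs(beta[cand]) > param * max(abs(beta))])
    if (length(idx) == 0) {
      stop("empty selection: no |beta| extremum exceeds ", param,
           " * max|beta|; lower the threshold or use mode = 'top_k'",
           call. = FALSE)
    }
  }
  wavelength_subset(idx, profile$wavelengths, method = "rc",
                    params = list(mode = mode, param = param,
                                  ncomp = profile$ncomp))
}

#' Construct a wavelength subset
#'
#' @param indices Band indices (1-based); deduplicated and sorted.
#' @param wavelengths Full band grid the indices refer to.
#' @param method Provenance tag: "rc", "interval" or "full".
#' @param params Selection parameters (free-form list).
#' @return Object of class `wavelength_subset`.
#' @export
wavelength_subset <- function(indices, wavelengths,
                              method = c("rc", "interval", "full"),
                              params = list()) {
  method <- match.arg(method)
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1 || min(indices) < 1 ||
      max(indices) > length(wavelengths)) {
    stop("subset indices out of range", call. = FALSE)
  }
  structure(list(indices = indices, wavelengths = wavelengths[indices],
                 method = method, params = params,
                 n_bands = length(wavelengths)),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat(sprintf("<wavelength_subset> %d of %d bands (%s), %.1f-%.1f nm\n",
              length(x$indices), x$n_bands, x$method,
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Serialize a wavelength subset to JSON
#' @param subset A `wavelength_subset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wavelength_subset <- function(subset, path) {
  stopifnot(inherits(subset, "wavelength_subset"))
  jsonlite::write_json(
    list(indices = subset$indices, wavelengths = subset$wavelengths,
         method = subset$method, params = subset$params,
         n_bands = subset$n_bands),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a wavelength subset from JSON
#' @param path JSON path written by [write_wavelength_subset()].
#' @param wavelengths Full band grid the subset indexes into.
#' @return A `wavelength_subset`.
#' @export
read_wavelength_subset <- function(path, wavelengths) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(wavelengths) != obj$n_bands) {
    stop("grid consistency error: subset was built on ", obj$n_bands,
         " bands, supplied grid has ", length(wavelengths), call. = FALSE)
  }
  wavelength_subset(obj$indices, wavelengths, method = obj$method,
                    params = as.list(obj$params))
}

#' Refit a PLSR on a wavelength subset
#'
#' Convenience wrapper: subsets the bands, fits [fit_plsr()], and stamps the
#' subset on the returned model so predictions accept full-grid input.
#'
#' @param X `spectra_matrix` or matrix on the full grid.
#' @param y Response vector.
#' @param subset A `wavelength_subset`.
#' @param ncomp Passed to [fit_plsr()].
#' @param cv_folds Passed to [fit_plsr()].
#' @return Fitted `carptex_model` with the subset applied.
#' @export
fit_plsr_subset <- function(X, y, subset, ncomp = "cv", cv_folds = 5) {
  stopifnot(inherits(subset, "wavelength_subset"))
  rx <- resolve_xy(X, y)
  model <- fit_plsr(rx$X[, subset$indices, drop = FALSE], y,
                    ncomp = ncomp, cv_folds = cv_folds)
  model$wavelengths <- rx$wavelengths
  model$subset <- subset$indices
  model
}
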