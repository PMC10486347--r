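# Calibration, Savitzky-Golay smoothing, ROI averaging, spectra matrices.

#' Construct a spectra matrix
#'
#' The X matrix of every calibration model: one mean ROI reflectance spectrum
#' per sample for a single skin region. Rows are ordered by `sample_id`.
#'
#' @param X Numeric matrix, n_samples x n_bands.
#' @param wavelengths Band grid (nm), strictly increasing.
#' @param sample_ids Character vector, one unique id per row.
#' @param region One of [muscle_regions()].
#' @return Object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(X, wavelengths, sample_ids, region) {
  X <- as.matrix(X)
  assert_region(region)
  if (length(wavelengths) != ncol(X)) {
    stop("wavelength grid length does not match spectra columns", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (length(sample_ids) != nrow(X)) {
    stop("one sample_id per spectra row required", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample_id in spectra matrix", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("spectra contain non-finite values", call. = FALSE)
  ord <- order(sample_ids)
  X <- X[ord, , drop = FALSE]
  rownames(X) <- sample_ids[ord]
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 sample_ids = sample_ids[ord], region = region),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> region=%s, %d samples x %d bands (%.1f-%.1f nm)\n",
              x$region, nrow(x$X), ncol(x$X),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Tidy a spectra matrix into long format
#' @param x A `spectra_matrix`.
#' @param ... Unused.
#' @return Tibble with sample_id, region, wavelength, reflectance.
#' @export
as_tibble.spectra_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids, times = ncol(x$X)),
    region = x$region,
    wavelength = rep(x$wavelengths, each = nrow(x$X)),
    reflectance = as.vector(x$X)
  )
}

#' Reflectance calibration with black/white correction
#'
#' Converts raw intensity to percent relative reflectance using
#' `I = (I0 - D) / (W - D) * 100`, where `I0` is the raw cube, `D` the dark
#' image (0 % reflectance) and `W` the white reference (100 % reflectance).
#'
#' @param raw A `spectral_cube` with `kind == "raw"`.
#' @param refs A [reference_pair()] sharing the cube's shape.
#' @return A reflectance `spectral_cube`.
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(refs, "reference_pair"))
  if (!identical(dim(raw$data), dim(refs$white))) {
    stop("reference shape does not match cube shape", call. = FALSE)
  }
  denom <- refs$white - refs$dark
  n_bad <- sum(denom <= .Machine$double.eps)
  if (n_bad > 0) {
    stop("calibration error: white - dark not positive at ", n_bad,
         " element(s)", call. = FALSE)
  }
  out <- (raw$data - refs$dark) / denom * 100
  spectral_cube(out, raw$wavelengths, kind = "reflectance", meta = raw$meta)
}

#' Invert the reflectance calibration
#'
#' Maps a reflectance cube back to raw intensity under a given reference pair:
#' `I0 = I/100 * (W - D) + D`. Used by the synthetic generator to emit
#' raw-intensity cubes.
#'
#' @param cube Reflectance `spectral_cube`.
#' @param refs A [reference_pair()].
#' @return A raw-intensity `spectral_cube`.
#' @export
uncalibrate_reflectance <- function(cube, refs) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(refs, "reference_pair"))
  raw <- cube$data / 100 * (refs$white - refs$dark) + refs$dark
  spectral_cube(raw, cube$wavelengths, kind = "raw", meta = cube$meta)
}

# Dense B x B Savitzky-Golay smoothing operator (includes the asymmetric
# end-point filters), built from signal::sgolay projection matrices.
sg_operator <- function(n_bands, window, polyorder) {
  if (window %% 2 == 0) stop("SG window must be odd", call. = FALSE)
  if (window <= polyorder) stop("SG window must exceed polyorder", call. = FALSE)
  if (window > n_bands) stop("SG window exceeds number of bands", call. = FALSE)
  F <- unclass(signal::sgolay(p = polyorder, n = window))
  half <- (window - 1) / 2
  M <- matrix(0, n_bands, n_bands)
  for (i in seq_len(n_bands)) {
    if (i <= half) {
      M[i, 1:window] <- F[i, ]
    } else if (i > n_bands - half) {
      M[i, (n_bands - window + 1):n_bands] <- F[window - (n_bands - i), ]
    } else {
      M[i, (i - half):(i + half)] <- F[half + 1, ]
    }
  }
  M
}

#' Savitzky-Golay smoothing along the spectral axis
#'
#' Applies SG polynomial smoothing to each spectrum independently; spatial
#' structure is untouched. Works on numeric vectors, matrices
#' (rows = spectra), `spectra_matrix`, and `spectral_cube` objects.
#'
#' @param x Object to smooth.
#' @param window Odd window length (default 11).
#' @param polyorder Polynomial order (default 2), must be < window.
#' @param ... Passed between methods.
#' @return Same shape/class as `x`.
#' @export
sg_smooth <- function(x, window = 11, polyorder = 2, ...) {
  UseMethod("sg_smooth")
}

#' @export
sg_smooth.numeric <- function(x, window = 11, polyorder = 2, ...) {
  as.vector(sg_smooth.matrix(matrix(x, nrow = 1), window, polyorder))
}

#' @export
sg_smooth.matrix <- function(x, window = 11, polyorder = 2, ...) {
  M <- sg_operator(ncol(x), window, polyorder)
  out <- x %*% t(M)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
sg_smooth.spectra_matrix <- function(x, window = 11, polyorder = 2, ...) {
  x$X <- sg_smooth.matrix(x$X, window, polyorder)
  x
}

#' @export
sg_smooth.spectral_cube <- function(x, window = 11, polyorder = 2, ...) {
  d <- dim(x$data)
  flat <- matrix(x$data, nrow = d[1] * d[2], ncol = d[3])
  sm <- sg_smooth.matrix(flat, window, polyorder)
  x$data <- array(sm, dim = d)
  x
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean over all pixels inside the ROI window.
#'
#' @param cube A `spectral_cube`.
#' @param roi An [roi_spec()] lying fully inside the raster.
#' @return Numeric vector of length `n_bands(cube)`.
#' @export
extract_roi_mean <- function(cube, roi) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(roi, "roi_spec"))
  d <- dim(cube$data)
  r1 <- roi$row0 + roi$height - 1L
  c1 <- roi$col0 + roi$width - 1L
  if (r1 > d[1] || c1 > d[2]) {
    stop("ROI geometry error: window [", roi$row0, ":", r1, ", ",
         roi$col0, ":", c1, "] exceeds raster ", d[1], " x ", d[2],
         call. = FALSE)
  }
  sub <- cube$data[roi$row0:r1, roi$col0:c1, , drop = FALSE]
  apply(sub, 3, mean)
}

#' Assemble a spectra matrix from per-sample spectra
#'
#' @param spectra Named list (names = sample ids) of equal-length numeric
#'   spectra, or a matrix with rownames as sample ids.
#' @param wavelengths Shared band grid.
#' @param region Region label.
#' @return A `spectra_matrix` with rows in canonical sample order.
#' @export
build_spectra_matrix <- function(spectra, wavelengths, region) {
  if (is.list(spectra)) {
    lens <- lengths(spectra)
    if (length(unique(lens)) != 1) {
      stop("grid consistency error: spectra differ in length", call. = FALSE)
    }
    X <- do.call(rbind, spectra)
    ids <- names(spectra)
  } else {
    X <- as.matrix(spectra)
    ids <- rownames(X)
  }
  if (is.null(ids)) stop("sample ids required (names or rownames)", call. = FALSE)
  spectra_matrix(X, wavelengths, ids, region)
}
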