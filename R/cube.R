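# Spectral cube container and cube/reference constructors.

#' Construct a spectral cube
#'
#' A hyperspectral cube holds one raster per band. `data` is a 3-D array with
#' dimensions (rows, cols, bands); `wavelengths` gives the band-centre
#' wavelength in nm for each band slice.
#'
#' @param data Numeric 3-D array, dim = c(rows, cols, bands).
#' @param wavelengths Strictly increasing numeric vector, one entry per band.
#' @param kind Either "raw" (instrument intensity) or "reflectance" (percent
#'   relative reflectance, nominally 0-100).
#' @param meta Free-form provenance list.
#' @return Object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths, kind = c("reflectance", "raw"),
                          meta = list()) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3-D array (rows, cols, bands)", call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3]) {
    stop("wavelength vector length (", length(wavelengths),
         ") does not match band count (", dim(data)[3], ")", call. = FALSE)
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  }
  if (kind == "reflectance") {
    if (any(!is.finite(data))) {
      stop("reflectance cube contains non-finite values", call. = FALSE)
    }
    n_out <- sum(data < 0 | data > 100)
    if (n_out > 0) meta$n_out_of_range <- n_out
  }
  structure(
    list(data = data, wavelengths = wavelengths, kind = kind, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' Number of bands in a cube
#' @param cube A `spectral_cube`.
#' @return Integer band count.
#' @export
n_bands <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  dim(cube$data)[3]
}

#' Tidy a spectral cube into long format
#'
#' @param x A `spectral_cube`.
#' @param ... Unused.
#' @return Tibble with columns row, col, wavelength, value.
#' @export
as_tibble.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    row = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    wavelength = rep(x$wavelengths, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' White/dark reference pair for reflectance calibration
#'
#' The white reference is the image of a ~100 % reflectance panel; the dark
#' image is acquired with the lens capped (0 % reflectance). Both must share
#' the cube's shape and satisfy white > dark at every element.
#'
#' @param white,dark Numeric arrays with the shape of the cube they calibrate.
#' @return Object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark) {
  if (!identical(dim(white), dim(dark))) {
    stop("white and dark references must share dimensions", call. = FALSE)
  }
  n_bad <- sum(white <= dark)
  if (n_bad > 0) {
    stop("calibration undefined: white <= dark at ", n_bad, " element(s)",
         call. = FALSE)
  }
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' Rectangular region of interest
#'
#' 1-based top-left corner plus extent; the ROI covers rows
#' `row0 .. row0 + height - 1` and the analogous columns. The study default
#' window is 200 x 200 pixels.
#'
#' @param row0,col0 Top-left pixel (1-based).
#' @param height,width Extent in pixels (>= 1).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(row0, col0, height = 200, width = 200) {
  stopifnot(row0 >= 1, col0 >= 1, height >= 1, width >= 1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}
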