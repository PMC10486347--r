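# Pixel-wise prediction maps and their rendering.

#' Construct a prediction map
#'
#' @param values rows x cols numeric matrix of predicted indicator values
#'   (NA outside the mask).
#' @param indicator Indicator name.
#' @param mask Logical rows x cols matrix (TRUE = foreground), or NULL for
#'   all pixels.
#' @param model_id Free-form provenance string.
#' @param colormap Two anchor colours (low, high); default blue -> orange.
#' @return Object of class `prediction_map` with the linear `value_range`
#'   computed over masked pixels.
#' @export
prediction_map <- function(values, indicator, mask = NULL, model_id = "",
                           colormap = c(low = "#2166AC", high = "#F28E2B")) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(identical(dim(mask), dim(values)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  inside <- values[mask]
  if (any(!is.finite(inside))) {
    stop("non-finite prediction inside mask", call. = FALSE)
  }
  structure(list(values = values, indicator = indicator, mask = mask,
                 model_id = model_id, colormap = colormap,
                 value_range = range(inside)),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> %s, %d x %d px, range [%.4g, %.4g]\n",
              x$indicator, nrow(x$values), ncol(x$values),
              x$value_range[1], x$value_range[2]))
  invisible(x)
}

#' Apply a fitted model to every pixel of a cube
#'
#' Contract: the value at each pixel equals `predict(model, <that pixel's
#' spectrum>)`; vectorization is an implementation detail. Predictions are in
#' the target's original (raw indicator) units via the model's stored inverse
#' target scaling.
#'
#' @param cube Calibrated reflectance `spectral_cube` on the model's grid.
#' @param model A `carptex_model`.
#' @param mask Optional logical rows x cols foreground mask.
#' @param indicator Indicator label for the map (default from provenance).
#' @return A `prediction_map`.
#' @export
predict_pixelwise <- function(cube, model, mask = NULL, indicator = model$kind) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(model, "carptex_model"))
  if (n_bands(cube) != length(model$wavelengths)) {
    stop("grid consistency error: cube has ", n_bands(cube),
         " bands; model grid has ", length(model$wavelengths), call. = FALSE)
  }
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  vals <- matrix(NA_real_, d[1], d[2])
  idx <- if (is.null(mask)) seq_len(d[1] * d[2]) else which(mask)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  vals[idx] <- predict(model, flat[idx, , drop = FALSE])
  prediction_map(vals, indicator, mask = mask,
                 model_id = paste0(model$kind, "/",
                                   length(model$subset %||% model$wavelengths),
                                   "wl"))
}

map_colours <- function(t, colormap) {
  lo <- grDevices::col2rgb(colormap[[1]]) / 255
  hi <- grDevices::col2rgb(colormap[[2]]) / 255
  cbind(lo[1] + t * (hi[1] - lo[1]),
        lo[2] + t * (hi[2] - lo[2]),
        lo[3] + t * (hi[3] - lo[3]))
}

#' Render a prediction map to a PNG file
#'
#' Linear colour mapping from the map's value range: blue at the minimum,
#' orange at the maximum; masked-out pixels are white. A vertical colourbar
#' is appended on the right. Byte-deterministic for identical inputs.
#'
#' @param map A `prediction_map`.
#' @param path Output PNG path; a sidecar JSON (`<path>.json`) records vmin,
#'   vmax, indicator and model id.
#' @param colorbar Append the colourbar strip? (default TRUE)
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, colorbar = TRUE) {
  stopifnot(inherits(map, "prediction_map"))
  v <- map$values
  rng <- map$value_range
  t <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
    matrix(0.5, nrow(v), ncol(v))
  tv <- as.vector(t)
  img <- array(1, dim = c(nrow(v), ncol(v), 3))
  ok <- which(!is.na(tv))
  cols <- map_colours(tv[ok], map$colormap)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ok] <- cols[, ch]
    img[, , ch] <- plane
  }
  if (colorbar) {
    bar_t <- seq(1, 0, length.out = nrow(v))
    bar_cols <- map_colours(bar_t, map$colormap)
    gap <- array(1, dim = c(nrow(v), 2, 3))
    bar <- array(0, dim = c(nrow(v), 8, 3))
    for (ch in 1:3) bar[, , ch] <- matrix(bar_cols[, ch], nrow(v), 8)
    img <- array(c(sapply(1:3, function(ch) {
      cbind(img[, , ch], gap[, , ch], bar[, , ch])
    })), dim = c(nrow(v), ncol(v) + 10, 3))
  }
  png::writePNG(img, path)
  jsonlite::write_json(
    list(vmin = rng[1], vmax = rng[2], indicator = map$indicator,
         model_id = map$model_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Summary statistics of a prediction map
#'
#' @param map A `prediction_map`.
#' @param quantiles Quantile thresholds; for each `q` the fraction of masked
#'   pixels strictly above the q-quantile is reported.
#' @return One-row tibble: n_pixels, mean, sd, min, max and one
#'   `frac_above_q*` column per threshold.
#' @export
map_statistics <- function(map, quantiles = c(0.9)) {
  stopifnot(inherits(map, "prediction_map"))
  v <- map$values[map$mask]
  out <- tibble::tibble(
    indicator = map$indicator, n_pixels = length(v),
    mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v)
  )
  for (q in quantiles) {
    thr <- stats::quantile(v, q, names = FALSE)
    out[[sprintf("frac_above_q%02d", round(100 * q))]] <- mean(v > thr)
  }
  out
}

#' Tidy a prediction map
#' @param x A `prediction_map`.
#' @param ... Unused.
#' @return Tibble with row, col, value (masked pixels NA).
#' @export
as_tibble.prediction_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Plot a prediction map
#'
#' ggplot2 raster of the predicted indicator, blue (low) to orange (high).
#'
#' @param object A `prediction_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_map <- function(object, ...) {
  df <- as_tibble.prediction_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = object$colormap[[1]],
                                 high = object$colormap[[2]],
                                 na.value = "white",
                                 limits = object$value_range,
                                 name = object$indicator) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an RC profile
#'
#' Beta-coefficient profile over wavelength with the selection threshold
#' band, in the style of RC wavelength-selection figures.
#'
#' @param object An `rc_profile`.
#' @param subset Optional `wavelength_subset` to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rc_profile <- function(object, subset = NULL, ...) {
  df <- tidy.rc_profile(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength,
                                        y = .data$beta)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient") +
    ggplot2::theme_minimal()
  if (!is.null(subset)) {
    sel <- df[subset$indices, ]
    p <- p + ggplot2::geom_point(data = sel, colour = "#F28E2B", size = 1.6)
  }
  p
}
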