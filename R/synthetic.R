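# Synthetic skin-spectra and texture generator.
#
# The generator emulates the statistical structure the analysis assumes:
# region-specific reflectance baselines with the observed visible/NIR shape
# (global trough near 430 nm, 600-780 nm plateau, water-related dip near
# 970-980 nm, monotone-rising dorsal curves, mean reflectance ordered
# gluteal > pectoral > abdominal > dorsal), plus a small set of latent
# "chemistry" components that drive both the spectra (through smooth spectral
# loadings) and the eight texture indicators (through a linear mixing map with
# an optional quadratic term). Everything downstream is testable against the
# returned ground truth.

#' Generator configuration
#'
#' @param n_samples Number of fish (>= 2).
#' @param n_bands Bands on the default grid (default 600 over 400-1000 nm).
#' @param regions Subset of [muscle_regions()] to generate.
#' @param n_latent Latent components (default 4: bumps near 500/780/980 nm
#'   plus one broad slope component).
#' @param noise_sd_spectral I.i.d. Gaussian band noise, reflectance-% units.
#' @param noise_sd_texture Gaussian indicator noise, standardized units.
#' @param nonlinearity In \[0, 1\]; scales a quadratic term in the first
#'   latent score added to springiness, resilience and brittleness.
#' @param two_cluster If TRUE the first latent score is bimodal, giving the
#'   two-cluster structure seen in indicator PCA.
#' @param seed Integer; fully determines the output.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_samples, n_bands = 600,
                             regions = muscle_regions(), n_latent = 4,
                             noise_sd_spectral = 0.5, noise_sd_texture = 0.05,
                             nonlinearity = 0, two_cluster = FALSE, seed = 1) {
  if (n_samples < 2) stop("n_samples must be at least 2", call. = FALSE)
  stopifnot(n_bands >= 10, n_latent >= 1, n_latent <= 4,
            noise_sd_spectral >= 0, noise_sd_texture >= 0,
            nonlinearity >= 0, nonlinearity <= 1)
  regions <- vapply(regions, assert_region, "")
  structure(list(n_samples = as.integer(n_samples),
                 n_bands = as.integer(n_bands),
                 regions = unname(regions), n_latent = as.integer(n_latent),
                 noise_sd_spectral = noise_sd_spectral,
                 noise_sd_texture = noise_sd_texture,
                 nonlinearity = nonlinearity, two_cluster = two_cluster,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Control points defining each region's baseline reflectance curve (%R).
# Non-dorsal regions: global minimum at 430 nm, rise to a 600-780 nm plateau,
# fall to a local minimum at 970 nm, rise afterwards. Dorsal: minimum at
# 430 nm then monotone non-decreasing to 1000 nm, and the lowest mean.
baseline_controls <- function(region) {
  switch(region,
    gluteal = list(wl = c(400, 430, 500, 600, 780, 970, 1000),
                   v = c(22, 18, 38, 52, 52, 44, 47)),
    pectoral = list(wl = c(400, 430, 500, 600, 780, 970, 1000),
                    v = c(17, 14, 30, 42, 42, 35, 38)),
    abdominal = list(wl = c(400, 430, 500, 600, 780, 970, 1000),
                     v = c(15, 12, 26, 36, 36, 30, 32.5)),
    dorsal = list(wl = c(400, 430, 600, 780, 1000),
                  v = c(13, 10, 14, 18, 24))
  )
}

#' Region baseline reflectance spectrum
#'
#' Deterministic smooth baseline for one skin region on the default band
#' grid, satisfying the observed shape contracts (trough at 430 nm, plateau,
#' NIR dip, region mean ordering; monotone rise for dorsal).
#'
#' @param region One of [muscle_regions()].
#' @param n_bands Grid size (default 600).
#' @return Numeric reflectance spectrum (length `n_bands`).
#' @export
make_region_baseline <- function(region, n_bands = 600) {
  assert_region(region)
  cp <- baseline_controls(region)
  wl <- default_band_grid(n_bands)
  # piecewise cubic smoothstep between control points: zero slope at every
  # control point, so each segment is monotone and extrema sit exactly on
  # the controls (no spline overshoot)
  seg <- findInterval(wl, cp$wl, rightmost.closed = TRUE, all.inside = TRUE)
  t <- (wl - cp$wl[seg]) / (cp$wl[seg + 1] - cp$wl[seg])
  t <- pmin(pmax(t, 0), 1)
  s <- 3 * t^2 - 2 * t^3
  cp$v[seg] + (cp$v[seg + 1] - cp$v[seg]) * s
}

# Latent spectral loadings: Gaussian bumps near the discussed absorption
# features (~500, 780, 980 nm) plus one broad slope component. Amplitudes in
# reflectance-% per unit (standard normal) score.
latent_basis <- function(wavelengths, n_latent = 4, amplitude = 5) {
  centers <- c(500, 780, 980)
  widths <- c(25, 35, 20)
  basis <- matrix(0, n_latent, length(wavelengths))
  for (k in seq_len(min(n_latent, 3))) {
    basis[k, ] <- exp(-(wavelengths - centers[k])^2 / (2 * widths[k]^2))
  }
  if (n_latent >= 4) {
    basis[4, ] <- (wavelengths - mean(wavelengths)) /
      (max(wavelengths) - min(wavelengths))
  }
  basis * amplitude
}

# Fixed mixing map latent scores -> 8 indicators (rows follow
# texture_indicators()); every indicator loads on at least one component.
mixing_weights <- function(n_latent = 4) {
  W <- rbind(
    gumminess    = c(1.0, 0.3, 0.0, 0.0),
    springiness  = c(0.0, 1.0, 0.0, 0.2),
    cohesiveness = c(0.5, 0.0, 0.8, 0.0),
    resilience   = c(0.0, 0.4, 1.0, 0.0),
    hardness     = c(0.8, 0.0, 0.0, 0.5),
    brittleness  = c(0.0, 0.6, 0.4, 0.6),
    adhesiveness = c(0.3, 0.0, 0.0, 1.0),
    chewiness    = c(0.9, 0.4, 0.3, 0.0)
  )
  W[, seq_len(n_latent), drop = FALSE]
}

# Indicators receiving the quadratic (in score 1) term when nonlinearity > 0.
quadratic_loadings <- function() {
  q <- stats::setNames(rep(0, 8), texture_indicators())
  q[c("springiness", "resilience", "brittleness")] <- 0.8
  q
}

# Bands where a bump component's loading exceeds half its maximum; the sparse
# ground truth that RC selection should recover. The slope component is
# spectrally global and has no sparse support (NA entry).
active_band_sets <- function(wavelengths, n_latent = 4) {
  basis <- latent_basis(wavelengths, n_latent)
  out <- vector("list", n_latent)
  for (k in seq_len(n_latent)) {
    if (k <= 3) {
      out[[k]] <- which(abs(basis[k, ]) > 0.5 * max(abs(basis[k, ])))
    } else {
      out[[k]] <- NA
    }
  }
  out
}

#' Bands that drive one indicator, per the generator's ground truth
#'
#' The spectral signature of an indicator is the mixing-weighted sum of the
#' latent loading curves; its active bands are those where the absolute
#' signature exceeds half its maximum. This is the sparse truth that
#' wavelength selection is expected to recover.
#'
#' @param ground_truth `ground_truth` element of [generate_dataset()] output.
#' @param indicator One of [texture_indicators()].
#' @return Integer vector of band indices.
#' @export
indicator_active_bands <- function(ground_truth, indicator) {
  indicator <- match.arg(indicator, texture_indicators())
  w <- ground_truth$mixing[indicator, ]
  sig <- abs(drop(w %*% ground_truth$basis))
  which(sig > 0.5 * max(sig))
}

draw_scores <- function(n, n_latent, two_cluster) {
  s <- matrix(stats::rnorm(n * n_latent), n, n_latent)
  if (two_cluster) {
    grp <- rep(c(-1.2, 1.2), length.out = n)
    s[, 1] <- s[, 1] * 0.6 + grp
  }
  s
}

indicator_values <- function(scores, config) {
  W <- mixing_weights(config$n_latent)
  Y <- scores %*% t(W)
  if (config$nonlinearity > 0) {
    q <- quadratic_loadings()
    Y <- Y + config$nonlinearity * (scores[, 1]^2 - 1) %o% q
  }
  colnames(Y) <- texture_indicators()
  Y
}

#' Generate a linked spectra + texture dataset
#'
#' Per region: latent scores are drawn per sample, pushed through the
#' spectral basis (added to the region baseline, plus band noise) and through
#' the indicator mixing map (plus indicator noise). The full ground truth is
#' returned so recovery can be tested.
#'
#' @param config A [generator_config()].
#' @return List with `spectra` (named list of `spectra_matrix` per region),
#'   `texture` (tibble, one row per sample x region), and `ground_truth`
#'   (basis, mixing weights, per-region scores, active band sets,
#'   nonlinear indicator names).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  wl <- default_band_grid(config$n_bands)
  basis <- latent_basis(wl, config$n_latent)
  ids <- sprintf("S%04d", seq_len(config$n_samples))
  with_seed(config$seed, {
    spectra <- list()
    scores_by_region <- list()
    texture_rows <- list()
    for (region in config$regions) {
      s <- draw_scores(config$n_samples, config$n_latent, config$two_cluster)
      base <- make_region_baseline(region, config$n_bands)
      X <- matrix(base, config$n_samples, config$n_bands, byrow = TRUE) +
        s %*% basis
      if (config$noise_sd_spectral > 0) {
        X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd_spectral),
                        nrow = nrow(X))
      }
      Y <- indicator_values(s, config)
      if (config$noise_sd_texture > 0) {
        Y <- Y + matrix(stats::rnorm(length(Y), sd = config$noise_sd_texture),
                        nrow = nrow(Y))
      }
      spectra[[region]] <- spectra_matrix(X, wl, ids, region)
      scores_by_region[[region]] <- s
      texture_rows[[region]] <- tibble::tibble(sample_id = ids, region = region,
                                               tibble::as_tibble(Y))
    }
    texture <- validate_texture_table(dplyr::bind_rows(texture_rows))
    nl <- if (config$nonlinearity > 0) {
      names(which(quadratic_loadings() > 0))
    } else character(0)
    list(
      spectra = spectra,
      texture = texture,
      ground_truth = list(
        wavelengths = wl, basis = basis,
        mixing = mixing_weights(config$n_latent),
        scores = scores_by_region,
        active_bands = active_band_sets(wl, config$n_latent),
        nonlinear_indicators = nl,
        config = config
      )
    )
  })
}

# Smooth spatial random field: white noise blurred by a separable Gaussian
# kernel (reflected edges), rescaled to unit sd.
smooth_field <- function(rows, cols, smoothness = 5) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (smoothness <= 0) return(z)
  half <- max(1L, ceiling(2 * smoothness))
  k <- stats::dnorm(seq(-half, half), sd = smoothness)
  k <- k / sum(k)
  pad_conv <- function(m) {
    idx <- c(rev(seq_len(half)), seq_len(nrow(m)),
             nrow(m) - seq_len(half) + 1)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(j - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
    out
  }
  z <- pad_conv(z)
  z <- t(pad_conv(t(z)))
  z / stats::sd(as.vector(z))
}

#' Generate a full synthetic cube with per-pixel ground truth
#'
#' Latent scores vary over pixels as a smooth random field; each pixel
#' spectrum is baseline + field scores x basis + noise. Ground-truth
#' per-pixel indicator rasters come from the same mixing map.
#'
#' @param config A [generator_config()]; its first `regions` entry is used.
#' @param rows,cols Raster size in pixels.
#' @param field_sd Pixel-to-pixel sd of the latent field (0 gives a spatially
#'   constant cube).
#' @param smoothness Gaussian blur sd (pixels) of the latent field.
#' @param refs Optional [reference_pair()]; when supplied, a raw-intensity
#'   cube obtained by inverting the calibration equation is returned as well.
#' @return List with `cube` (reflectance `spectral_cube`), `truth` (list of
#'   per-indicator ground-truth rasters), `scores` (rows x cols x n_latent
#'   array), and optionally `raw`.
#' @export
generate_cube <- function(config, rows, cols, field_sd = 1, smoothness = 5,
                          refs = NULL) {
  stopifnot(inherits(config, "generator_config"), rows >= 1, cols >= 1)
  region <- config$regions[1]
  wl <- default_band_grid(config$n_bands)
  basis <- latent_basis(wl, config$n_latent)
  with_seed(config$seed, {
    scores <- array(0, dim = c(rows, cols, config$n_latent))
    if (field_sd > 0) {
      for (k in seq_len(config$n_latent)) {
        scores[, , k] <- smooth_field(rows, cols, smoothness) * field_sd
      }
    }
    smat <- matrix(scores, nrow = rows * cols, ncol = config$n_latent)
    base <- make_region_baseline(region, config$n_bands)
    flat <- matrix(base, rows * cols, config$n_bands, byrow = TRUE) +
      smat %*% basis
    if (config$noise_sd_spectral > 0) {
      flat <- flat + matrix(stats::rnorm(length(flat),
                                         sd = config$noise_sd_spectral),
                            nrow = nrow(flat))
    }
    cube <- spectral_cube(array(flat, dim = c(rows, cols, config$n_bands)),
                          wl, kind = "reflectance")
    Y <- indicator_values(smat, config)
    truth <- lapply(stats::setNames(seq_len(ncol(Y)), colnames(Y)),
                    function(j) matrix(Y[, j], rows, cols))
    out <- list(cube = cube, truth = truth, scores = scores)
    if (!is.null(refs)) out$raw <- uncalibrate_reflectance(cube, refs)
    out
  })
}
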