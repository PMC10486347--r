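# Data splitting, target standardization, model evaluation and ranking,
# and statistical characterization of the texture indicators.

#' Split samples into calibration and prediction sets
#'
#' @param n_samples Total sample count (>= 4).
#' @param fraction Calibration fraction in (0, 1); default 0.75.
#' @param seed Seed for the random strategy.
#' @param strategy "random" (default) or "kennard_stone" (deterministic,
#'   requires `X`).
#' @param X Spectra matrix for Kennard-Stone distances.
#' @return List with integer vectors `calibration` and `prediction`
#'   (disjoint, covering 1..n).
#' @export
split_dataset <- function(n_samples, fraction = 0.75, seed = 1,
                          strategy = c("random", "kennard_stone"), X = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_samples >= 4, fraction > 0, fraction < 1)
  n_c <- round(fraction * n_samples)
  if (n_c < 2 || n_c > n_samples - 1) {
    stop("fraction yields an empty or degenerate set", call. = FALSE)
  }
  if (strategy == "random") {
    cal <- sort(with_seed(seed, sample.int(n_samples, n_c)))
  } else {
    if (is.null(X)) stop("kennard_stone requires X", call. = FALSE)
    Xm <- if (inherits(X, "spectra_matrix")) X$X else as.matrix(X)
    stopifnot(nrow(Xm) == n_samples)
    cal <- sort(kennard_stone(Xm, n_c))
  }
  list(calibration = cal, prediction = setdiff(seq_len(n_samples), cal))
}

# Classic Kennard-Stone: seed with the two most distant points, then
# repeatedly add the point maximizing its minimum distance to the selection.
kennard_stone <- function(X, n_select) {
  D <- as.matrix(stats::dist(X))
  sel <- as.vector(arrayInd(which.max(D), dim(D)))
  while (length(sel) < n_select) {
    rest <- setdiff(seq_len(nrow(X)), sel)
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

#' Standardize targets on calibration statistics
#'
#' Z-scores `y` using its own mean and (sample) sd; the returned scaler is
#' applied unchanged to prediction-set values so both sets live on the
#' calibration scale.
#'
#' @param y Calibration target values (variance > 0).
#' @return List with `scaler` (mean, sd) and `y_std`.
#' @export
standardize_targets <- function(y) {
  m <- mean(y); s <- stats::sd(y)
  if (!is.finite(s) || s == 0) {
    stop("degenerate target: zero variance", call. = FALSE)
  }
  list(scaler = list(mean = m, sd = s), y_std = (y - m) / s)
}

#' Apply a target scaler
#' @param y Values to standardize.
#' @param scaler Scaler from [standardize_targets()].
#' @return Standardized values.
#' @export
apply_scaler <- function(y, scaler) (y - scaler$mean) / scaler$sd

#' Invert a target scaler
#' @param y_std Standardized values.
#' @param scaler Scaler from [standardize_targets()].
#' @return Values on the original scale.
#' @export
invert_scaler <- function(y_std, scaler) y_std * scaler$sd + scaler$mean

model_fitters <- function() {
  list(
    plsr = function(X, y, opts) fit_plsr(X, y,
      ncomp = opts$ncomp %||% "cv", cv_folds = opts$cv_folds %||% 5),
    ipls = function(X, y, opts) fit_ipls(X, y,
      n_intervals = opts$n_intervals %||% 10, ncomp = opts$ncomp %||% "cv",
      cv_folds = opts$cv_folds %||% 5),
    sipls = function(X, y, opts) fit_sipls(X, y,
      n_intervals = opts$n_intervals %||% 10,
      combo_size = opts$combo_size %||% 2, ncomp = opts$ncomp %||% "cv",
      cv_folds = opts$cv_folds %||% 5),
    bipls = function(X, y, opts) fit_bipls(X, y,
      n_intervals = opts$n_intervals %||% 10, ncomp = opts$ncomp %||% "cv",
      cv_folds = opts$cv_folds %||% 5),
    lssvm = function(X, y, opts) fit_lssvm(X, y,
      grid_points = opts$grid_points %||% 20,
      cv_folds = opts$cv_folds %||% 5),
    bpann = function(X, y, opts) fit_bpann(X, y,
      hidden_size = opts$hidden_size %||% 10, seed = opts$seed %||% 1)
  )
}

#' Canonical model-kind order
#' @return Character vector of the six model kinds.
#' @export
model_kinds <- function() c("plsr", "ipls", "sipls", "bipls", "lssvm", "bpann")

#' Fit and evaluate calibration models for one (region, indicator) cell
#'
#' Splits the samples, z-scores the indicator on the calibration set, fits
#' each requested model on the standardized target, and reports r_c, RMSEC,
#' r_p, RMSEP (standardized-target units) per model.
#'
#' @param spectra `spectra_matrix` for one region.
#' @param texture Texture table covering the spectra's samples.
#' @param indicator One of [texture_indicators()].
#' @param models Model kinds to fit (subset of [model_kinds()]).
#' @param subset Optional `wavelength_subset` applied to all models.
#' @param split List with `fraction`, `seed`, `strategy` (see
#'   [split_dataset()]), or a precomputed split list.
#' @param model_opts Named list of per-fitter options (n_intervals,
#'   combo_size, grid_points, hidden_size, cv_folds, seed, ncomp).
#' @param keep_models Keep the fitted model objects in the result?
#' @return Tibble with one row per model: region, indicator, model, n_wl,
#'   factors, r_c, rmsec, r_p, rmsep, n_c, n_p; fitted models (and the target
#'   scaler) are attached as a list column `fit` when `keep_models = TRUE`.
#' @export
evaluate_models <- function(spectra, texture, indicator,
                            models = model_kinds(), subset = NULL,
                            split = list(fraction = 0.75, seed = 1,
                                         strategy = "random"),
                            model_opts = list(), keep_models = FALSE) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  indicator <- match.arg(indicator, texture_indicators())
  models <- match.arg(models, model_kinds(), several.ok = TRUE)
  tex <- dplyr::filter(texture, .data$region == spectra$region)
  tex <- tex[match(spectra$sample_ids, tex$sample_id), ]
  if (any(is.na(tex$sample_id))) {
    stop("join error: spectra sample(s) absent from texture table",
         call. = FALSE)
  }
  y <- tex[[indicator]]
  n <- nrow(spectra$X)
  sp <- if (!is.null(split$calibration)) {
    split
  } else {
    split_dataset(n, fraction = split$fraction %||% 0.75,
                  seed = split$seed %||% 1,
                  strategy = split$strategy %||% "random", X = spectra$X)
  }
  Xall <- spectra$X
  if (!is.null(subset)) {
    stopifnot(inherits(subset, "wavelength_subset"))
    Xall <- Xall[, subset$indices, drop = FALSE]
  }
  Xc <- Xall[sp$calibration, , drop = FALSE]
  Xp <- Xall[sp$prediction, , drop = FALSE]
  std <- standardize_targets(y[sp$calibration])
  yc <- std$y_std
  yp <- apply_scaler(y[sp$prediction], std$scaler)
  fitters <- model_fitters()
  rows <- purrr::map(models, function(kind) {
    fit_obj <- fitters[[kind]](Xc, yc, model_opts)
    pred_c <- predict(fit_obj, Xc)
    pred_p <- predict(fit_obj, Xp)
    R <- model_factor_count(fit_obj)
    n_wl_fit <- if (is.null(fit_obj$subset)) ncol(Xall) else length(fit_obj$subset)
    tibble::tibble(
      region = spectra$region, indicator = indicator, model = kind,
      n_wl = n_wl_fit,
      factors = R,
      r_c = r_coefficient(yc, pred_c),
      rmsec = rmsec(yc, pred_c, R),
      r_p = r_coefficient(yp, pred_p),
      rmsep = rmsep(yp, pred_p),
      n_c = length(sp$calibration), n_p = length(sp$prediction),
      fit = if (keep_models) {
        list(list(model = fit_obj, scaler = std$scaler, split = sp,
                  subset = subset))
      } else list(NULL)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_models) out$fit <- NULL
  out
}

#' Retain the best model per (region, indicator)
#'
#' Argmax of r_p within each (region, indicator) cell; ties broken by lower
#' RMSEP, then by canonical model-kind order.
#'
#' @param reports Tibble of evaluation rows (as from [evaluate_models()]).
#' @return Tibble with one retained row per cell.
#' @export
rank_models <- function(reports) {
  stopifnot(all(c("region", "indicator", "model", "r_p", "rmsep") %in%
                  names(reports)))
  if (nrow(reports) == 0) stop("missing-result error: no reports", call. = FALSE)
  reports |>
    dplyr::mutate(.model_rank = match(.data$model, model_kinds())) |>
    dplyr::group_by(.data$region, .data$indicator) |>
    dplyr::arrange(dplyr::desc(.data$r_p), .data$rmsep, .data$.model_rank,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".model_rank")
}

#' PCA of the texture indicators for one region
#'
#' PCA on the standardized 8-indicator matrix; reports the fraction of
#' variance per component and the sample scores.
#'
#' @param texture Texture table.
#' @param region Region to characterize.
#' @return List with `variance_explained` (fractions summing to 1), `scores`
#'   tibble (sample_id + PC columns), and `rank`.
#' @export
indicator_pca <- function(texture, region) {
  assert_region(region)
  tex <- dplyr::filter(validate_texture_table(texture),
                       .data$region == !!region)
  if (nrow(tex) < 3) stop("need at least 3 samples for PCA", call. = FALSE)
  M <- as.matrix(tex[texture_indicators()])
  sds <- apply(M, 2, stats::sd)
  keep <- sds > 0
  pca <- stats::prcomp(M[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  scores <- tibble::as_tibble(pca$x)
  scores$sample_id <- tex$sample_id
  list(variance_explained = ve,
       scores = dplyr::relocate(scores, "sample_id"),
       rank = sum(pca$sdev > 1e-10))
}

#' Spearman correlation structure of the texture indicators
#'
#' 8 x 8 Spearman rank correlation matrix (average ranks on ties) with
#' two-sided p-values and significance flags at `alpha` (no multiplicity
#' correction applied).
#'
#' @param texture Texture table.
#' @param region Region to characterize.
#' @param alpha Significance level (default 0.05).
#' @return List with matrices `rho`, `p_value`, `significant`, and the tidy
#'   tibble `pairs` (one row per unordered indicator pair).
#' @export
indicator_spearman <- function(texture, region, alpha = 0.05) {
  assert_region(region)
  tex <- dplyr::filter(validate_texture_table(texture),
                       .data$region == !!region)
  if (nrow(tex) < 5) stop("need at least 5 samples", call. = FALSE)
  M <- as.matrix(tex[texture_indicators()])
  k <- ncol(M)
  rho <- stats::cor(M, method = "spearman")
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p[i, j] <- p[j, i] <- suppressWarnings(
        stats::cor.test(M[, i], M[, j], method = "spearman",
                        exact = FALSE)$p.value)
    }
  }
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pairs <- tibble::tibble(
    indicator_a = colnames(rho)[ut[, 1]],
    indicator_b = colnames(rho)[ut[, 2]],
    rho = rho[ut], p_value = p[ut],
    significant = p[ut] < alpha
  )
  list(rho = rho, p_value = p, significant = p < alpha, pairs = pairs)
}
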