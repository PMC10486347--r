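# Small programmatic fixtures shared across test files.

random_cube <- function(rows = 4, cols = 4, bands = 5, seed = 1,
                        kind = "reflectance") {
  set.seed(seed)
  spectral_cube(array(runif(rows * cols * bands) * 100, c(rows, cols, bands)),
                default_band_grid(bands), kind = kind)
}

# Dataset with linear signal confined to known bands: y depends only on the
# columns in `active`, everything else is noise.
sparse_signal_data <- function(n = 80, p = 100, active = 21:30,
                               coef = 0.8, noise = 0.05, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, active, drop = FALSE] %*% rep(coef, length(active))) +
    rnorm(n) * noise
  list(X = X, y = y, active = active)
}

toy_texture_table <- function(n = 3, regions = muscle_regions(), seed = 1) {
  set.seed(seed)
  rows <- expand.grid(sample_id = sprintf("S%03d", seq_len(n)),
                      region = regions, stringsAsFactors = FALSE)
  vals <- matrix(rnorm(nrow(rows) * 8), nrow(rows), 8,
                 dimnames = list(NULL, texture_indicators()))
  tibble::as_tibble(cbind(rows, vals))
}
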