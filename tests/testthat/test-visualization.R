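# Pixel-wise prediction maps and rendering.

fit_small_model <- function(bands = 20, seed = 41) {
  set.seed(seed)
  X <- matrix(rnorm(60 * bands), 60, bands)
  y <- drop(X %*% seq(-1, 1, length.out = bands)) + 0.05 * rnorm(60)
  fit_plsr(spectra_matrix(X + 50, default_band_grid(bands),
                          sprintf("S%02d", 1:60), "dorsal"), y + 10, ncomp = 4)
}

test_that("pixel-wise prediction equals the naive per-pixel loop", {
  set.seed(42)
  bands <- 20
  model <- fit_small_model(bands)
  cube <- spectral_cube(array(rnorm(8 * 8 * bands) + 50, c(8, 8, bands)),
                        default_band_grid(bands))
  map <- predict_pixelwise(cube, model, indicator = "gumminess")
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- predict(model, matrix(cube$data[i, j, ], 1))
  }
  expect_identical(map$values, oracle)
})

test_that("a spatially constant cube maps to the single-spectrum prediction", {
  bands <- 20
  model <- fit_small_model(bands)
  spec <- rnorm(bands) + 50
  cube <- spectral_cube(array(rep(spec, each = 36), c(6, 6, bands)),
                        default_band_grid(bands))
  map <- predict_pixelwise(cube, model)
  expect_equal(unname(as.vector(map$values)),
               rep(predict(model, matrix(spec, 1)), 36), tolerance = 1e-12)
  expect_equal(map$value_range[1], map$value_range[2])
})

test_that("masked pixels are excluded from predictions and value range", {
  bands <- 20
  model <- fit_small_model(bands)
  cube <- spectral_cube(array(rnorm(6 * 6 * bands) + 50, c(6, 6, bands)),
                        default_band_grid(bands))
  mask <- matrix(TRUE, 6, 6); mask[1:3, 1] <- FALSE
  full <- predict_pixelwise(cube, model)
  masked <- predict_pixelwise(cube, model, mask = mask)
  expect_true(all(is.na(masked$values[1:3, 1])))
  inside <- masked$values[mask]
  expect_equal(masked$value_range, range(inside))
  # forcing extremes into the masked-out pixels must not widen the range
  expect_true(all(inside >= masked$value_range[1] &
                    inside <= masked$value_range[2]))
  expect_equal(masked$values[mask], full$values[mask], tolerance = 1e-12)
  expect_error(predict_pixelwise(cube, model,
                                 mask = matrix(FALSE, 6, 6)), "empty mask")
})

test_that("grid mismatch between cube and model is rejected", {
  model <- fit_small_model(20)
  cube <- spectral_cube(array(1, c(4, 4, 19)), default_band_grid(19))
  expect_error(predict_pixelwise(cube, model), "consistency")
})

test_that("rendering is deterministic, monotone blue-to-orange, and uniform
           for constant maps", {
  m <- prediction_map(matrix(c(0, 0, 1, 1), 2, 2), "hardness")
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_map(m, p1, colorbar = FALSE)
  render_map(m, p2, colorbar = FALSE)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  img <- png::readPNG(p1)
  cols <- unique(matrix(img, 4, 3))
  expect_equal(nrow(cols), 2)
  # low value bluer, high value more orange/red
  low <- img[1, 1, ]; high <- img[1, 2, ]
  expect_gt(low[3], high[3])   # blue channel
  expect_gt(high[1], low[1])   # red channel

  const <- prediction_map(matrix(5, 3, 3), "hardness")
  pc <- withr::local_tempfile(fileext = ".png")
  render_map(const, pc, colorbar = FALSE)
  imgc <- png::readPNG(pc)
  expect_equal(length(unique(matrix(imgc, 9, 3)[, 1])), 1)
  # sidecar JSON carries the linear scale endpoints
  side <- jsonlite::read_json(paste0(pc, ".json"))
  expect_equal(side$vmin, 5)
  expect_equal(side$vmax, 5)
})

test_that("map statistics summarize masked pixels and quantile exceedance", {
  const <- prediction_map(matrix(2, 4, 4), "chewiness")
  st <- map_statistics(const)
  expect_equal(st$sd, 0)
  expect_equal(st$mean, 2)

  set.seed(43)
  vals <- matrix(rnorm(400), 20, 20)
  st2 <- map_statistics(prediction_map(vals, "chewiness"),
                        quantiles = c(0.9))
  expect_equal(st2$frac_above_q90, 0.1, tolerance = 0.01)

  # map mean tracks the generator's ground truth
  cfg <- generator_config(2, n_bands = 60, regions = "dorsal",
                          noise_sd_spectral = 0.1, seed = 44)
  cb <- generate_cube(cfg, 16, 16)
  d <- generate_dataset(generator_config(150, n_bands = 60,
                                         regions = "dorsal", seed = 45))
  tex <- dplyr::filter(d$texture, region == "dorsal")
  y <- tex$gumminess[match(d$spectra$dorsal$sample_ids, tex$sample_id)]
  model <- fit_plsr(d$spectra$dorsal, y)
  map <- predict_pixelwise(cb$cube, model, indicator = "gumminess")
  expect_equal(map_statistics(map)$mean, mean(cb$truth$gumminess),
               tolerance = 0.1)
})

test_that("pixel-wise prediction commutes with cropping and noise ordering
           holds", {
  bands <- 30
  model <- fit_small_model(bands)
  cfgf <- function(noise, seed = 46) generator_config(
    2, n_bands = bands, regions = "dorsal", noise_sd_spectral = noise,
    seed = seed)
  cb <- generate_cube(cfgf(0.2), 10, 10)
  full <- predict_pixelwise(cb$cube, model)
  crop <- spectral_cube(cb$cube$data[3:7, 2:9, , drop = FALSE],
                        cb$cube$wavelengths)
  cropped <- predict_pixelwise(crop, model)
  expect_identical(full$values[3:7, 2:9], cropped$values)

  # per-pixel RMSE against ground truth decreases with generator noise
  d <- generate_dataset(generator_config(150, n_bands = bands,
                                         regions = "dorsal", seed = 47))
  tex <- dplyr::filter(d$texture, region == "dorsal")
  y <- tex$chewiness[match(d$spectra$dorsal$sample_ids, tex$sample_id)]
  mreal <- fit_plsr(d$spectra$dorsal, y)
  rmse_at <- vapply(c(0, 1, 4), function(noise) {
    cbn <- generate_cube(cfgf(noise), 12, 12)
    mp <- predict_pixelwise(cbn$cube, mreal)
    sqrt(mean((mp$values - cbn$truth$chewiness)^2))
  }, 0)
  expect_true(all(diff(rmse_at) > 0))
})

test_that("autoplot returns ggplot objects for maps and RC profiles", {
  m <- prediction_map(matrix(rnorm(12), 3, 4), "gumminess")
  expect_s3_class(autoplot(m), "ggplot")
  dat <- sparse_signal_data(n = 40, p = 25, active = 5:7, seed = 48)
  prof <- compute_rc_profile(dat$X, dat$y, ncomp = 2)
  expect_s3_class(autoplot(prof, subset = select_by_rc(prof, "top_k", 5)),
                  "ggplot")
  expect_named(tidy(prof), c("wavelength", "beta"))
})
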