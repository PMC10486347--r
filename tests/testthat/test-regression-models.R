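# The six calibration models behind the shared fit/predict contract.

test_that("PLSR fits an exact single-band linear relation perfectly", {
  x <- matrix(seq(1, 10, length.out = 20), ncol = 1)
  y <- drop(2 * x)
  m <- fit_plsr(x, y, ncomp = 1)
  expect_equal(m$fitted, y, tolerance = 1e-10)
  expect_equal(rmsec(y, m$fitted, 1), 0, tolerance = 1e-9)
})

test_that("PLSR at full rank matches the least-squares oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 8), 30, 8)
    y <- drop(X %*% rnorm(8) + rnorm(30))
    m <- fit_plsr(X, y, ncomp = 8)
    ols <- lm.fit(cbind(1, X), y)$fitted.values
    expect_equal(m$fitted, unname(ols), tolerance = 1e-8)
  }
})

test_that("duplicating a band leaves PLSR predictions unchanged at rank", {
  # refit oracle: the duplicate adds no information, so once the latent space
  # spans the column space the fits coincide and the |beta| mass is split
  # across the duplicated pair
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(X %*% rnorm(6) + 0.1 * rnorm(40))
  m1 <- fit_plsr(X, y, ncomp = 6)
  m2 <- fit_plsr(cbind(X, X[, 2]), y, ncomp = 6)
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-8)
  expect_length(m2$fit$beta, 7)
  expect_equal(m2$fit$beta[2], m2$fit$beta[7], tolerance = 1e-8)
  expect_equal(m2$fit$beta[2] + m2$fit$beta[7], m1$fit$beta[2],
               tolerance = 1e-6)
})

test_that("PLSR score vectors are orthogonal and ncomp is validated", {
  set.seed(5)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- rnorm(25)
  m <- fit_plsr(X, y, ncomp = 5)
  G <- crossprod(m$fit$Tm)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(fit_plsr(X, y, ncomp = 30), "ncomp")
  expect_error(fit_plsr(X, rep(1, 25)), "degenerate")
})

test_that("cross-validated ncomp tracks the true latent dimension", {
  set.seed(6)
  n <- 120
  scores <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * 50), 3, 50)
  X <- scores %*% load + 0.01 * matrix(rnorm(n * 50), n)
  y <- drop(scores %*% c(1, -1, 0.5)) + 0.01 * rnorm(n)
  m <- fit_plsr(X, y, ncomp = "cv")
  expect_gte(m$hyperparams$ncomp, 3)
  expect_lte(m$hyperparams$ncomp, 6)
})

test_that("iPLS finds the informative interval and honors the tie rule", {
  dat <- sparse_signal_data(n = 80, p = 100, active = 21:30, seed = 11)
  m <- fit_ipls(dat$X, dat$y, n_intervals = 10)
  expect_equal(m$hyperparams$interval, 3)
  expect_identical(m$subset, 21:30)

  # n_intervals = 1 degenerates to full-spectrum PLSR
  m1 <- fit_ipls(dat$X, dat$y, n_intervals = 1, ncomp = 3)
  mf <- fit_plsr(dat$X, dat$y, ncomp = 3)
  expect_equal(m1$fitted, mf$fitted, tolerance = 1e-10)

  # two identical informative intervals -> lowest index wins
  set.seed(12)
  Xd <- matrix(rnorm(60 * 20), 60, 20)
  Xd[, 11:20] <- Xd[, 1:10]
  yd <- drop(Xd[, 1:10] %*% rep(1, 10))
  md <- fit_ipls(Xd, yd, n_intervals = 2, ncomp = 2)
  expect_equal(md$hyperparams$interval, 1)
})

test_that("SiPLS finds the informative interval pair and degenerates correctly", {
  set.seed(13)
  X <- matrix(rnorm(80 * 100), 80, 100)
  y <- drop(X[, 11:20] %*% rep(0.7, 10)) + drop(X[, 61:70] %*% rep(0.7, 10)) +
    rnorm(80) * 0.05
  m <- fit_sipls(X, y, n_intervals = 10, combo_size = 2)
  expect_identical(sort(m$hyperparams$combination), c(2L, 7L))
  expect_identical(m$subset, sort(c(11:20, 61:70)))

  # combo_size == n_intervals is the full spectrum
  mfull <- fit_sipls(X, y, n_intervals = 4, combo_size = 4, ncomp = 3)
  mp <- fit_plsr(X, y, ncomp = 3)
  expect_equal(mfull$fitted, mp$fitted, tolerance = 1e-10)

  # combo_size 1 equals iPLS
  ms1 <- fit_sipls(X, y, n_intervals = 10, combo_size = 1, ncomp = 3)
  mi <- fit_ipls(X, y, n_intervals = 10, ncomp = 3)
  expect_equal(ms1$fitted, mi$fitted, tolerance = 1e-12)
  expect_error(fit_sipls(X, y, 10, 11), "combo_size")
  expect_error(fit_sipls(X, y, 20, 10, max_combos = 100), "budget")
})

test_that("BiPLS eliminates noise intervals before informative ones", {
  dat <- sparse_signal_data(n = 80, p = 100, active = 21:30, seed = 14)
  m <- fit_bipls(dat$X, dat$y, n_intervals = 10)
  expect_true(3 %in% m$hyperparams$survivors)
  expect_false(3 %in% m$hyperparams$trace)

  # two intervals, one pure noise -> informative one survives
  set.seed(15)
  X2 <- matrix(rnorm(60 * 20), 60, 20)
  y2 <- drop(X2[, 1:10] %*% rep(1, 10)) + rnorm(60) * 0.01
  m2 <- fit_bipls(X2, y2, n_intervals = 2, ncomp = 2)
  expect_identical(m2$hyperparams$survivors, 1L)
})

test_that("interval-family winners attain the searched-family RMSEC minimum", {
  dat <- sparse_signal_data(n = 50, p = 40, active = 11:20, seed = 16)
  iv <- make_intervals(40, 5)
  rms <- vapply(iv, function(idx) {
    mod <- fit_plsr(dat$X[, idx, drop = FALSE], dat$y, ncomp = 2)
    rmsec(dat$y, mod$fitted, 2)
  }, 0)
  m <- fit_ipls(dat$X, dat$y, n_intervals = 5, ncomp = 2)
  expect_equal(min(rms), rmsec(dat$y, m$fitted, 2), tolerance = 1e-10)
  expect_equal(which.min(rms), m$hyperparams$interval)

  combos <- utils::combn(5, 2, simplify = FALSE)
  rms2 <- vapply(combos, function(cmb) {
    idx <- sort(unlist(iv[cmb]))
    mod <- fit_plsr(dat$X[, idx, drop = FALSE], dat$y, ncomp = 2)
    rmsec(dat$y, mod$fitted, 2)
  }, 0)
  ms <- fit_sipls(dat$X, dat$y, n_intervals = 5, combo_size = 2, ncomp = 2)
  expect_equal(min(rms2), rmsec(dat$y, ms$fitted, 2), tolerance = 1e-10)
})

test_that("LS-SVM matches a direct dense KKT solve", {
  for (n in c(3, 12, 30)) {
    set.seed(n)
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rnorm(n)
    gamma <- 10; sigma2 <- 2
    m <- fit_lssvm(X, y, gamma = gamma, sigma2 = sigma2)
    sc <- carptex:::standardize_xy(X, y)
    K <- carptex:::rbf_kernel(sc$Xs, sc$Xs, sigma2)
    A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
    sol <- solve(A, c(0, sc$ys_vec))
    oracle <- sc$ym + sc$ys * drop(K %*% sol[-1] + sol[1])
    expect_equal(m$fitted, oracle, tolerance = 1e-8)
  }
})

test_that("LS-SVM interpolates as regularization vanishes and localizes", {
  set.seed(21)
  X <- matrix(rnorm(15 * 3), 15, 3)
  y <- rnorm(15)
  m <- fit_lssvm(X, y, gamma = 1e9, sigma2 = 2)
  expect_equal(m$fitted, y, tolerance = 1e-5)

  # a test point equal to a training point with a tiny kernel width
  # predicts (nearly) that training target
  m2 <- fit_lssvm(X, y, gamma = 1e6, sigma2 = 1e-4)
  pred <- predict(m2, X[c(4, 9), , drop = FALSE])
  expect_equal(pred, y[c(4, 9)], tolerance = 1e-3)
})

test_that("LS-SVM grid search selects sensible hyperparameters", {
  set.seed(22)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- drop(sin(X[, 1]) + 0.5 * X[, 2]) + rnorm(60) * 0.05
  m <- fit_lssvm(X, y, grid_points = 8)
  expect_true(m$hyperparams$gamma > 1e-3 && m$hyperparams$gamma <= 1000)
  expect_true(m$hyperparams$sigma2 > 1e-3 && m$hyperparams$sigma2 <= 1000)
  expect_gt(r_coefficient(y, m$fitted), 0.9)
})

test_that("BP-ANN learns a noiseless linear map to r_c >= 0.99", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 1))
  m <- fit_bpann(X, y, seed = 3)
  lin <- lm.fit(cbind(1, X), y)$fitted.values # linear-regression oracle
  expect_gte(r_coefficient(y, m$fitted), 0.99)
  expect_gte(r_coefficient(unname(lin), m$fitted), 0.99)
  expect_lte(m$hyperparams$epochs, 1000)
})

test_that("BP-ANN is deterministic given the seed and stops at the goal", {
  set.seed(23)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rnorm(30)
  m1 <- fit_bpann(X, y, seed = 7)
  m2 <- fit_bpann(X, y, seed = 7)
  expect_identical(m1$fit, m2$fit)
  expect_identical(m1$fitted, m2$fitted)
  m3 <- fit_bpann(X, y, seed = 8)
  expect_false(identical(m1$fitted, m3$fitted))

  # zero-initialized net on an all-zero target meets the goal at epoch 0
  m0 <- fit_bpann(X, rep(0, 30), seed = 1, init = "zero")
  expect_identical(m0$hyperparams$epochs, 0L)
})

test_that("predict applies stored scaling, subsets, and row independence", {
  dat <- sparse_signal_data(n = 50, p = 30, active = 5:8, seed = 24)
  sub <- wavelength_subset(5:8, default_band_grid(30), "rc")
  m <- fit_plsr_subset(spectra_matrix(dat$X, default_band_grid(30),
                                      sprintf("S%02d", 1:50), "dorsal"),
                       dat$y, sub, ncomp = 2)
  set.seed(25)
  Xnew <- matrix(rnorm(6 * 30), 6, 30)
  p_full <- predict(m, Xnew)              # full grid in, subset applied
  p_sub <- predict(m, Xnew[, 5:8])        # pre-subset columns
  expect_identical(p_full, p_sub)
  # permuted rows give permuted predictions
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(predict(m, Xnew[perm, ]), p_full[perm], tolerance = 1e-12)
  expect_error(predict(m, Xnew[, 1:7]), "consistency")
  # predicting on the training design reproduces the stored fit
  expect_identical(predict(m, dat$X), m$fitted)
})

test_that("all models are scale-equivariant in the target", {
  set.seed(26)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(40) * 0.1
  c_ <- 7.3
  fits <- list(
    plsr = function(yy) fit_plsr(X, yy, ncomp = 3),
    ipls = function(yy) fit_ipls(X, yy, n_intervals = 2, ncomp = 2),
    lssvm = function(yy) fit_lssvm(X, yy, gamma = 50, sigma2 = 10),
    bpann = function(yy) fit_bpann(X, yy, seed = 5)
  )
  for (kind in names(fits)) {
    m1 <- fits[[kind]](y)
    m2 <- fits[[kind]](c_ * y)
    expect_equal(m2$fitted, c_ * m1$fitted, tolerance = 1e-6,
                 label = paste(kind, "fitted"))
  }
})

test_that("nonlinear generator regimes favour the nonlinear models", {
  wins <- 0L
  n_seeds <- 12
  for (seed in seq_len(n_seeds)) {
    cfg <- generator_config(120, n_bands = 60, regions = "dorsal",
                            nonlinearity = 1, noise_sd_texture = 0.05,
                            seed = seed)
    d <- generate_dataset(cfg)
    rep <- evaluate_models(d$spectra$dorsal, d$texture, "resilience",
                           models = c("plsr", "lssvm", "bpann"),
                           split = list(fraction = 0.75, seed = 1),
                           model_opts = list(grid_points = 8, seed = seed))
    rmse <- rep$rmsep
    if (min(rmse[rep$model != "plsr"]) < rmse[rep$model == "plsr"]) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins / n_seeds, 0.7)
})
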