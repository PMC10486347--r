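# Splitting, target standardization, metrics, ranking, indicator structure.

test_that("random splits are sized, disjoint, covering and seed-stable", {
  sp <- split_dataset(10, fraction = 0.7, seed = 4)
  expect_length(sp$calibration, 7)
  expect_length(sp$prediction, 3)
  expect_length(intersect(sp$calibration, sp$prediction), 0)
  expect_setequal(c(sp$calibration, sp$prediction), 1:10)
  expect_identical(sp, split_dataset(10, fraction = 0.7, seed = 4))
  expect_false(identical(sp, split_dataset(10, fraction = 0.7, seed = 5)))
  expect_error(split_dataset(3), "n_samples")
  expect_error(split_dataset(10, fraction = 0.05), "empty or degenerate")
})

test_that("Kennard-Stone takes the extreme points first", {
  # three collinear points: the two extremes must enter calibration first
  X <- matrix(c(0, 0, 1, 1, 10, 10), 3, 2, byrow = TRUE)
  expect_setequal(carptex:::kennard_stone(X, 2), c(1L, 3L))
  sp <- split_dataset(4, fraction = 0.5, strategy = "kennard_stone",
                      X = rbind(X, c(5, 5)))
  expect_setequal(sp$calibration, c(1L, 3L))
  expect_error(split_dataset(4, strategy = "kennard_stone"), "requires X")
})

test_that("target standardization round-trips and reuses calibration stats", {
  std <- standardize_targets(c(1, 2, 3))
  expect_equal(std$y_std, c(-1, 0, 1))
  expect_equal(std$scaler$sd, 1) # sample sd convention
  y <- rnorm(20)
  std2 <- standardize_targets(y)
  expect_equal(invert_scaler(std2$y_std, std2$scaler), y, tolerance = 1e-12)
  # prediction-set values use the calibration scaler, not their own
  y_new <- c(100, 200)
  expect_equal(apply_scaler(y_new, std$scaler), c(98, 198))
  expect_error(standardize_targets(rep(4, 5)), "degenerate")
})

test_that("rmsec and rmsep match hand-computed values", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(rmsec(y, y, 1), 0)
  expect_equal(rmsec(y, y + 1, 1), sqrt(5 / 3), tolerance = 1e-9)
  expect_equal(rmsec(y, y + 1, 3), sqrt(5), tolerance = 1e-9)
  expect_error(rmsec(y, y, 4), "N > R \\+ 1")

  expect_equal(rmsep(y, y), 0)
  expect_equal(rmsep(y, y + 1), 1)
  expect_equal(rmsep(c(0, 0), c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  # constant-shift identity
  for (c_ in c(-2.5, 0.3, 9)) expect_equal(rmsep(y, y + c_), abs(c_))
})

test_that("r_coefficient is affine-invariant and flags degenerate input", {
  set.seed(8)
  y <- rnorm(30)
  expect_equal(r_coefficient(y, y), 1)
  expect_equal(r_coefficient(y, 3.2 * y - 5), 1, tolerance = 1e-12)
  expect_equal(r_coefficient(y, -2 * y + 1), 1, tolerance = 1e-12)
  expect_error(r_coefficient(y, rep(mean(y), 30)), "degenerate")
  # printed-formula mode: small for good fits, not 1
  expect_lt(r_coefficient(y, y + 0.01 * rnorm(30), mode = "printed"), 0.1)
})

test_that("rank_models retains the highest r_p with the stated tie rules", {
  base <- tibble::tibble(
    region = "dorsal", indicator = "chewiness",
    model = c("plsr", "lssvm", "bpann"),
    r_p = c(0.90, 0.95, 0.93), rmsep = c(0.3, 0.2, 0.25)
  )
  expect_identical(rank_models(base)$model, "lssvm")

  tie <- base
  tie$r_p <- c(0.95, 0.95, 0.90)
  tie$rmsep <- c(0.3, 0.2, 0.1)
  expect_identical(rank_models(tie)$model, "lssvm")

  tie2 <- tie
  tie2$rmsep <- c(0.2, 0.2, 0.1)
  expect_identical(rank_models(tie2)$model, "plsr") # canonical kind order

  expect_identical(rank_models(base[2, ])$model, "lssvm")
  # invariant to report ordering
  expect_identical(rank_models(base[c(3, 1, 2), ]), rank_models(base))
})

test_that("evaluate_models reports coherent metrics and honors subsets", {
  cfg <- generator_config(60, n_bands = 80, regions = "pectoral", seed = 31)
  d <- generate_dataset(cfg)
  rep <- evaluate_models(d$spectra$pectoral, d$texture, "hardness",
                         models = c("plsr", "ipls"),
                         split = list(fraction = 0.75, seed = 2))
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$n_c + rep$n_p == 60))
  expect_true(all(rep$r_c >= 0 & rep$r_c <= 1))
  expect_true(all(rep$rmsec >= 0 & rep$rmsep >= 0))
  expect_equal(rep$n_wl, c(80, 8))

  sub <- wavelength_subset(1:20, d$spectra$pectoral$wavelengths, "rc")
  rep2 <- evaluate_models(d$spectra$pectoral, d$texture, "hardness",
                          models = "plsr", subset = sub,
                          split = list(fraction = 0.75, seed = 2))
  expect_equal(rep2$n_wl, 20)

  # samples missing from the texture table are a join error
  tex_missing <- d$texture[-3, ]
  expect_error(evaluate_models(d$spectra$pectoral, tex_missing, "hardness",
                               models = "plsr"), "join error")
})

test_that("indicator PCA reports variance fractions and degenerate ranks", {
  # perfectly collinear 8-D data lies on a single line -> PC1 fraction 1
  set.seed(32)
  t_ <- rnorm(40)
  tab <- tibble::tibble(sample_id = sprintf("S%02d", 1:40), region = "dorsal")
  for (k in seq_along(texture_indicators())) {
    tab[[texture_indicators()[k]]] <- t_ * k + k
  }
  p <- indicator_pca(tab, "dorsal")
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-9)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  expect_equal(p$rank, 1)

  # isotropic noise at large n -> fractions near 1/8 each
  tab2 <- toy_texture_table(n = 4000, regions = "gluteal", seed = 33)
  p2 <- indicator_pca(tab2, "gluteal")
  expect_true(all(abs(p2$variance_explained - 1 / 8) < 0.03))
})

test_that("two-cluster generator data separates along PC1", {
  cfg <- generator_config(150, n_bands = 40, regions = "dorsal",
                          two_cluster = TRUE, seed = 34)
  d <- generate_dataset(cfg)
  p <- indicator_pca(d$texture, "dorsal")
  km <- kmeans(p$scores$PC1, centers = 2, nstart = 5)
  # between-cluster separation dominates within-cluster spread
  expect_gt(km$betweenss / km$totss, 0.6)
})

test_that("indicator Spearman matrix matches base R and flags known pairs", {
  tab <- toy_texture_table(n = 100, regions = "abdominal", seed = 35)
  tab$springiness <- tab$gumminess            # duplicate -> rho 1
  tab$chewiness <- -3 * tab$hardness + 5      # monotone decreasing -> rho -1
  sp <- indicator_spearman(tab, "abdominal")
  expect_equal(sp$rho["gumminess", "springiness"], 1)
  expect_equal(sp$rho["hardness", "chewiness"], -1)
  expect_true(isSymmetric(sp$rho))
  expect_true(all(diag(sp$rho) == 1))
  expect_equal(nrow(sp$pairs), 28)

  # independent noise: |rho| modest, significance near the nominal rate
  tab2 <- toy_texture_table(n = 100, regions = "dorsal", seed = 36)
  sp2 <- indicator_spearman(tab2, "dorsal")
  off <- sp2$rho[upper.tri(sp2$rho)]
  expect_lt(max(abs(off)), 0.35)
  expect_lte(mean(sp2$pairs$significant), 0.25)
  ct <- cor.test(tab2$gumminess, tab2$hardness, method = "spearman",
                 exact = FALSE)
  expect_equal(sp2$rho["gumminess", "hardness"], unname(ct$estimate))
  expect_equal(sp2$p_value["gumminess", "hardness"], ct$p.value)
})
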