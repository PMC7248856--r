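test_that("two distinct samples give a rank-1 model: PC1 explains 100%", {
  x <- rbind(c(1, 2, 3), c(3, 2, 1))
  fit <- pca_fit(x, 1)
  expect_equal(fit$explained_var_pct[1], 100)
  expect_error(pca_fit(x, 2), "n_components")
  expect_error(pca_fit(x[1, , drop = FALSE], 1), "at least 2")
})

test_that("explained variances match a dense eigendecomposition oracle", {
  x <- matrix(c(2, 0, 1, 4, 1, 1, 0, 3, 5, 2, 2, 0), nrow = 4)
  fit <- pca_fit(x, 3)
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$all_var_pct, 100 * ev[1:3] / sum(ev), tolerance = 1e-10)

  # property: random small matrices agree with the eigensolver, the
  # loadings are orthonormal, and scores reproduce the centered data
  for (seed in 1:50) {
    set.seed(seed)
    m <- matrix(rnorm(30), 6, 5)
    fit <- pca_fit(m, 5)
    ev <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(fit$all_var_pct[1:3], 100 * ev[1:3] / sum(ev),
                 tolerance = 1e-8)
    expect_equal(crossprod(fit$loadings), diag(5), tolerance = 1e-8,
                 ignore_attr = TRUE)
    xc <- sweep(m, 2, colMeans(m))
    expect_equal(fit$scores, xc %*% fit$loadings, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(xc, tcrossprod(fit$scores, fit$loadings), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(fit$all_var_pct), 100, tolerance = 1e-6)
    expect_true(all(diff(fit$all_var_pct) <= 1e-12))
  }
})

test_that("pca agrees with prcomp and is invariant to sample order", {
  set.seed(3)
  m <- matrix(rnorm(80), 10, 8)
  fit <- pca_fit(m, 4)
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  expect_equal(abs(fit$loadings), abs(pr$rotation[, 1:4]),
               tolerance = 1e-8, ignore_attr = TRUE)

  perm <- sample(10)
  fit_p <- pca_fit(m[perm, ], 4)
  expect_equal(fit_p$all_var_pct, fit$all_var_pct, tolerance = 1e-10)
})

test_that("rank-1 mixing data put 100% on PC1 in every region", {
  cfg <- generator_config(noise_sd = 0)
  lad <- template_ladder(levels = c(10, 25, 40, 70), cfg = cfg)
  tab <- explained_variance_profile(
    lad, list(full = region_spec(4000, 650),
              split = region_spec(c(3050, 1800), c(2750, 650)),
              ch = region_spec(3050, 2750),
              fp = region_spec(1800, 650)), 2)
  expect_equal(nrow(tab), 8)
  pc1 <- tab$var_pct[tab$component == 1]
  expect_equal(pc1, rep(100, 4), tolerance = 1e-8)

  # single-region call reduces to pca_fit
  one <- explained_variance_profile(lad, list(fp = region_spec(1800, 650)), 2)
  direct <- pca_fit(crop_region(lad, region_spec(1800, 650)), 2)
  expect_equal(one$var_pct, direct$explained_var_pct)
})

test_that("oil types separate into distinct centroids in 3-PC score space", {
  cfg <- fp_config(seed = 4)
  lib <- build_endmember_library(4)
  sp <- list()
  for (oil in names(lib))
    for (b in paste0(oil, "-", 1:3))
      for (r in 1:2)
        sp[[length(sp) + 1]] <- synth_spectrum(lib[[oil]], cfg, b, r)
  set <- savgol_smooth(spectrum_set(sp))
  fit <- pca_fit(set, 3)
  oil <- factor(rep(names(lib), each = 6))
  centroids <- apply(fit$scores, 2, tapply, oil, mean)
  dmin <- min(dist(centroids))
  scatter <- mean(sqrt(tapply(rowSums(
    (fit$scores - centroids[oil, ])^2), oil, mean)))
  expect_gt(dmin, 3 * scatter)
})

test_that("loading-based selection finds a dominant variable first", {
  set.seed(8)
  n <- 40
  driver <- rnorm(n, sd = 10)
  x <- cbind(v1 = driver + rnorm(n, sd = 0.1),
             v2 = rnorm(n, sd = 0.4),
             v3 = rnorm(n, sd = 0.2))
  fit <- pca_fit(x, 3)
  sel <- select_wavenumbers_from_loadings(fit, k = 1, min_separation = 0,
                                          grid = c(30, 20, 10))
  expect_equal(sel$wavenumbers, 30)  # the dominant variable's position

  expect_error(select_wavenumbers_from_loadings(fit, k = 3, min_separation = 0,
                                                grid = c(30, 20, 10)),
               "separated loading maxima")
})

test_that("selection on the admixture set recovers the seven markers", {
  cfg <- fp_config(seed = 1)
  pset <- generate_classification_set(levels = c(0, 1, 3, 5, 10, 15, 20),
                                      cfg = cfg)
  pp <- preprocess_set(pset, preprocess_config(derivative_order = 0))
  fit <- pca_fit(pp, 3)
  sel <- select_wavenumbers_from_loadings(fit, k = 7)
  found <- sort(sel$wavenumbers, decreasing = TRUE)
  for (target in c(1744, 1464, 1377, 1155, 1119, 1096, 721))
    expect_lte(min(abs(found - target)), 8)
})
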