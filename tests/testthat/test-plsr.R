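make_mixture_data <- function(n = 13, p = 40, noise = 0, seed = 1) {
  # two fixed endmember profiles, linear volume mixing
  set.seed(seed)
  e1 <- abs(sin(seq_len(p) / 3)) + 0.2
  e2 <- abs(cos(seq_len(p) / 4)) + 0.1
  y <- seq(0, 60, length.out = n)
  X <- t(vapply(y, function(v) (1 - v / 100) * e1 + (v / 100) * e2,
                numeric(p)))
  if (noise > 0) X <- X + matrix(rnorm(n * p, 0, noise), n, p)
  list(X = X, y = y)
}

test_that("one factor recovers noise-free linear mixtures exactly", {
  d <- make_mixture_data()
  fit <- plsr_fit(d$X, d$y, 1)
  expect_equal(fit$fitted, d$y, tolerance = 1e-6)
  expect_equal(predict(fit, d$X), d$y, tolerance = 1e-6)
})

test_that("full-rank PLSR equals the least-squares solution", {
  set.seed(4)
  n <- 12; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  fit <- plsr_fit(X, y, p)
  Xc <- sweep(X, 2, colMeans(X))
  b_ls <- as.numeric(MASS::ginv(Xc) %*% (y - mean(y)))
  expect_equal(fit$regression_vector, b_ls, tolerance = 1e-6)
  expect_equal(fit$fitted, as.numeric(Xc %*% b_ls + mean(y)), tolerance = 1e-8)
})

test_that("nipals invariants: orthogonal scores, consistent predictions", {
  set.seed(5)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  fit <- plsr_fit(X, y, 5)
  G <- crossprod(fit$scores)
  expect_equal(G - diag(diag(G)), matrix(0, 5, 5), tolerance = 1e-8)
  # regression-vector prediction equals the sequential score expansion
  seq_pred <- fit$y_mean + as.numeric(fit$scores %*% fit$y_loadings)
  expect_equal(fit$fitted, seq_pred, tolerance = 1e-8)
  # determinism
  expect_identical(fit$regression_vector, plsr_fit(X, y, 5)$regression_vector)
})

test_that("rmsec is non-increasing in the number of factors", {
  set.seed(6)
  X <- matrix(rnorm(18 * 25), 18, 25)
  y <- rnorm(18)
  rmsec <- vapply(1:6, function(a) {
    f <- plsr_fit(X, y, a)
    sqrt(mean((f$fitted - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("preconditions reject constant y and oversized factor counts", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(plsr_fit(X, rep(3, 5), 1), "constant")
  expect_error(plsr_fit(X, 1:5, 5), "ncomp")
  fit <- plsr_fit(X, c(1, 3, 2, 5, 4), 2)
  expect_error(predict(fit, X[, 1:3]), "dimension")
  expect_error(predict(fit, X[0, , drop = FALSE]), "no samples")
})

test_that("predicting the training-mean spectrum returns the mean level", {
  d <- make_mixture_data(noise = 1e-3)
  fit <- plsr_fit(d$X, d$y, 3)
  expect_equal(predict(fit, matrix(colMeans(d$X), 1)), mean(d$y),
               tolerance = 1e-10)
})

test_that("a held-out noise-free blend is predicted exactly", {
  d <- make_mixture_data(n = 14)
  i <- which.min(abs(d$y - 25))
  fit <- plsr_fit(d$X[-i, ], d$y[-i], 1)
  expect_equal(predict(fit, d$X[i, , drop = FALSE]), d$y[i], tolerance = 0.01)
})

test_that("loo predictions are exact for collinear data and order-invariant", {
  d <- make_mixture_data(n = 3)
  expect_equal(loo_cv(d$X, d$y, 1), d$y, tolerance = 1e-6)

  dn <- make_mixture_data(n = 12, noise = 1e-3, seed = 2)
  r1 <- sort(dn$y - loo_cv(dn$X, dn$y, 2))
  perm <- c(5, 1, 12, 3, 8, 2, 11, 4, 10, 6, 9, 7)
  r2 <- sort(dn$y[perm] - loo_cv(dn$X[perm, ], dn$y[perm], 2))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("rmsecv exceeds rmsec on pure-noise responses", {
  worse <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(15 * 10), 15, 10)
    y <- rnorm(15)
    fit <- plsr_fit(X, y, 3)
    rmsec <- sqrt(mean((fit$fitted - y)^2))
    rmsecv <- sqrt(mean((loo_cv(X, y, 3) - y)^2))
    if (rmsecv >= rmsec) worse <- worse + 1L
  }
  expect_equal(worse, 20L)
})

test_that("figures of merit follow their closed forms", {
  y <- c(0, 10, 20, 30, 40)
  perfect <- figures_of_merit(y, y, y, n_factors = 4)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$offset, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmsec, 0)
  expect_equal(perfect$rmsecv, 0)

  biased <- figures_of_merit(y, y + 2)
  expect_equal(biased$slope, 1, tolerance = 1e-12)
  expect_equal(biased$offset, 2, tolerance = 1e-12)
  expect_equal(biased$rmsec, 2, tolerance = 1e-12)

  # arithmetic oracle on a 5-point toy set
  yt <- c(1, 3, 5, 10, 20)
  yp <- c(1.2, 2.7, 5.4, 9.8, 20.3)
  m <- figures_of_merit(yt, yp)
  slope_hand <- sum((yt - mean(yt)) * (yp - mean(yp))) / sum((yt - mean(yt))^2)
  expect_equal(m$slope, slope_hand, tolerance = 1e-12)
  expect_equal(m$offset, mean(yp) - slope_hand * mean(yt), tolerance = 1e-12)
  expect_equal(m$rmsec, sqrt(mean((yp - yt)^2)), tolerance = 1e-12)
  expect_equal(m$r2, cor(yt, yp)^2, tolerance = 1e-12)

  expect_error(figures_of_merit(rep(1, 5), yp), "zero variance")
  expect_error(figures_of_merit(yt, yp[1:3]), "equal length")
})

test_that("the calibration suite builds one model per brand pair", {
  cfg <- fp_config(seed = 12)
  set <- generate_design(design_table5(), cfg)
  tab <- run_calibration_suite(set, factors = 4)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$n, rep(13, 15))
  expect_setequal(unique(tab$rso_brand), paste0("RSO-", 1:3))
  expect_setequal(unique(tab$cao_brand), paste0("CAO-", 1:5))

  # noise-free ladders are recovered essentially exactly
  set0 <- generate_design(design_table5(), fp_config(seed = 12, noise_sd = 0))
  tab0 <- run_calibration_suite(set0, factors = 4)
  expect_true(all(tab0$rmsec < 0.1))

  expect_error(run_calibration_suite(set[set$meta$oil_type == "CAO"]),
               "no blend ladders")
})
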