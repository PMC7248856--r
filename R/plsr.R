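# NIPALS partial least squares regression --------------------------------

#' Fit a single-response PLSR model by NIPALS
#'
#' Both blocks are mean-centered; each factor takes its weight vector from
#' the X-y covariance (closed form for a single response), scores
#' `t = X w`, X-loading `p = X't / t't`, y-loading `q = y't / t't`, and
#' deflates both blocks. The regression vector in the original variable
#' space is `B = W (P'W)^{-1} q`. Entirely deterministic.
#'
#' @param X Numeric samples-by-variables matrix (or [spectrum_set()],
#'   transposed internally).
#' @param y Numeric response vector (% v/v adulterant here).
#' @param ncomp Number of latent factors `a <= min(n - 1, p)`.
#' @return An object of class `"oil_plsr"` with fields `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `regression_vector`, `x_mean`,
#'   `y_mean`, `fitted`, `ncomp`.
#' @export
plsr_fit <- function(X, y, ncomp = 4) {
  X <- set_to_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y must have one value per row of X")
  if (var(y) == 0) stop("y is constant; nothing to regress on")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop(sprintf("ncomp must lie in [1, %d]", min(n - 1, p)))
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5 * max(1, sqrt(sum(y^2)))) {
      # X carries no residual covariance with y (exact low-rank data):
      # keep the factors already extracted
      break
    }
    w <- w / nw
    t_sc <- E %*% w
    tt <- sum(t_sc^2)
    p_load <- crossprod(E, t_sc) / tt
    q[a] <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q[a] * t_sc
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t_sc
    used <- a
  }
  if (used == 0L) stop("X carries no covariance with y")
  if (used < ncomp) {
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    Tm <- Tm[, seq_len(used), drop = FALSE]
    q <- q[seq_len(used)]
    ncomp <- used
  }
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- as.numeric(sweep(X, 2, x_mean) %*% B + y_mean)
  structure(list(weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, regression_vector = as.numeric(B),
                 x_mean = x_mean, y_mean = y_mean,
                 fitted = fitted, y = y, ncomp = ncomp),
            class = "oil_plsr")
}

#' @export
print.oil_plsr <- function(x, ...) {
  cat(sprintf("<oil_plsr> %d factors, %d variables, n = %d\n",
              x$ncomp, length(x$regression_vector), length(x$y)))
  cat(sprintf("  RMSEC = %.4f\n", sqrt(mean((x$fitted - x$y)^2))))
  invisible(x)
}

#' @export
coef.oil_plsr <- function(object, ...) object$regression_vector

#' Predict adulterant levels from spectra
#'
#' `y_hat = (X - x_mean) . B + y_mean`. Predictions are not clipped:
#' values outside `[0, 100]` are returned as-is (and can be flagged
#' downstream), since clipping would bias error statistics.
#'
#' @param object An [plsr_fit()] model.
#' @param newdata Samples-by-variables matrix or [spectrum_set()].
#' @param ... Unused.
#' @return Numeric vector of predicted % v/v.
#' @export
predict.oil_plsr <- function(object, newdata, ...) {
  X <- set_to_matrix(newdata)
  if (!nrow(X)) stop("no samples to predict")
  if (ncol(X) != length(object$regression_vector))
    stop("variable dimension does not match the fitted model")
  as.numeric(sweep(X, 2, object$x_mean) %*% object$regression_vector +
               object$y_mean)
}

#' @export
fitted.oil_plsr <- function(object, ...) object$fitted

#' @export
residuals.oil_plsr <- function(object, ...) object$y - object$fitted

#' @export
plot.oil_plsr <- function(x, ...) {
  plot(x$y, x$fitted, xlab = "Actual (% v/v)", ylab = "Predicted (% v/v)", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validated PLSR predictions
#'
#' One refit per held-out sample at a fixed number of factors;
#' deterministic.
#'
#' @inheritParams plsr_fit
#' @return Numeric vector of out-of-fold predictions, one per sample.
#' @export
loo_cv <- function(X, y, ncomp = 4) {
  X <- set_to_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  vapply(seq_len(n), function(i) {
    fit <- plsr_fit(X[-i, , drop = FALSE], y[-i], ncomp)
    predict(fit, X[i, , drop = FALSE])
  }, numeric(1))
}

#' Calibration figures of merit
#'
#' `RMSEC = sqrt(mean((y_pred_cal - y_true)^2))` and likewise RMSECV over
#' the out-of-fold predictions. Slope and offset come from ordinary least
#' squares of predicted on actual (`predicted = slope * actual + offset`);
#' R-squared is the squared Pearson correlation of predicted vs actual.
#'
#' @param y_true Reference levels (% v/v), non-constant.
#' @param y_pred_cal Calibration (resubstitution) predictions.
#' @param y_pred_cv Out-of-fold predictions (optional).
#' @param n_factors Number of PLSR factors, carried into the output.
#' @return A one-row `data.frame` of class `"calibration_metrics"`:
#'   `slope`, `offset`, `r2`, `rmsec`, and when `y_pred_cv` is given
#'   `slope_cv`, `offset_cv`, `r2_cv`, `rmsecv`; plus `n_factors`.
#' @export
figures_of_merit <- function(y_true, y_pred_cal, y_pred_cv = NULL,
                             n_factors = NA_integer_) {
  if (length(y_pred_cal) != length(y_true))
    stop("y_true and y_pred_cal must have equal length")
  if (var(y_true) == 0) stop("y_true has zero variance")
  ols <- function(pred) {
    slope <- cov(y_true, pred) / var(y_true)
    c(slope = slope, offset = mean(pred) - slope * mean(y_true),
      r2 = cor(y_true, pred)^2)
  }
  cal <- ols(y_pred_cal)
  out <- data.frame(n_factors = n_factors,
                    slope = cal[["slope"]], offset = cal[["offset"]],
                    rmsec = sqrt(mean((y_pred_cal - y_true)^2)),
                    r2 = cal[["r2"]])
  if (!is.null(y_pred_cv)) {
    if (length(y_pred_cv) != length(y_true))
      stop("y_true and y_pred_cv must have equal length")
    cv <- ols(y_pred_cv)
    out$slope_cv <- cv[["slope"]]
    out$offset_cv <- cv[["offset"]]
    out$rmsecv <- sqrt(mean((y_pred_cv - y_true)^2))
    out$r2_cv <- cv[["r2"]]
  }
  class(out) <- c("calibration_metrics", "data.frame")
  out
}

#' Fit the per-brand-pair PLSR calibration suite
#'
#' Builds one PLSR model per (RSO brand, CAO brand) pair from the blend
#' ladders in `set`: levels 0 (the pure CAO of that brand) up to
#' `max_level`, preprocessed with `cfg`. With the 5 x 3 brand design this
#' is the 15-model layout of a full calibration campaign.
#'
#' @param set A [spectrum_set()] containing the blend ladders and pure
#'   CAO samples (e.g. from [generate_design()]).
#' @param factors Latent factors per model (default 4).
#' @param cfg A [preprocess_config()] applied to the whole set first.
#' @param max_level Highest blend level entering calibration (% v/v).
#' @return A `data.frame` with one [figures_of_merit()] row per pair,
#'   keyed by `rso_brand` and `cao_brand`, plus the calibration size `n`.
#' @export
run_calibration_suite <- function(set, factors = 4,
                                  cfg = preprocess_config(),
                                  max_level = 50) {
  stopifnot(inherits(set, "spectrum_set"))
  pp <- preprocess_set(set, cfg)
  meta <- pp$meta
  blends <- meta$oil_type == "BLEND" & meta$blend_fraction_v <= max_level
  pairs <- unique(meta[blends, c("base_brand", "adulterant_brand")])
  if (!nrow(pairs)) stop("set contains no blend ladders")
  pairs <- pairs[order(pairs$adulterant_brand, pairs$base_brand), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cb <- pairs$base_brand[i]; rb <- pairs$adulterant_brand[i]
    sel <- (blends & meta$base_brand == cb & meta$adulterant_brand == rb) |
      (meta$oil_type == "CAO" & meta$blend_fraction_v == 0 &
         meta$base_brand == cb)
    if (sum(sel) < factors + 2)
      stop(sprintf("incomplete ladder for pair (%s, %s): %d samples",
                   rb, cb, sum(sel)))
    X <- t(pp$absorbance[, sel, drop = FALSE])
    y <- meta$blend_fraction_v[sel]
    fit <- plsr_fit(X, y, factors)
    cv <- loo_cv(X, y, factors)
    fom <- figures_of_merit(y, fit$fitted, cv, factors)
    cbind(data.frame(rso_brand = rb, cao_brand = cb, n = length(y),
                     stringsAsFactors = FALSE),
          as.data.frame(fom))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
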