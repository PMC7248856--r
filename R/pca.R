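# Principal component analysis for spectral exploration ------------------

set_to_matrix <- function(x) {
  if (inherits(x, "spectrum_set")) t(x$absorbance) else as.matrix(x)
}

#' Fit a PCA to spectra or a plain matrix
#'
#' Column-mean centering followed by singular value decomposition of the
#' centered sample-by-variable matrix. Explained variances are
#' `100 * sigma_i^2 / sum(sigma_j^2)` over all `min(n - 1, p)` components.
#' Loadings carry a deterministic sign convention: the element of largest
#' magnitude in each loading is positive.
#'
#' @param x A [spectrum_set()] (samples = spectra, variables = wavenumbers)
#'   or a numeric samples-by-variables matrix.
#' @param n_components Number of components to retain
#'   (`<= min(n - 1, p)`).
#' @return An object of class `"spectra_pca"` with fields `mean`,
#'   `loadings` (variables x components, orthonormal), `scores`
#'   (samples x components), `explained_var_pct` (retained components),
#'   `all_var_pct` (all components), `wavenumbers` (when fitted to a set).
#' @export
pca_fit <- function(x, n_components = 3) {
  wn <- if (inherits(x, "spectrum_set")) x$wavenumbers else NULL
  X <- set_to_matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("PCA needs at least 2 samples")
  kmax <- min(n - 1, p)
  if (n_components < 1 || n_components > kmax)
    stop(sprintf("n_components must lie in [1, %d]", kmax))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  d2 <- sv$d^2
  total <- sum(d2)
  all_var_pct <- 100 * d2[seq_len(kmax)] / total
  load <- sv$v[, seq_len(n_components), drop = FALSE]
  scores <- Xc %*% load
  # sign convention: largest-|element| of each loading positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- rownames(X)
  structure(list(mean = mu, loadings = load, scores = scores,
                 explained_var_pct = all_var_pct[seq_len(n_components)],
                 all_var_pct = all_var_pct,
                 n_components = n_components, wavenumbers = wn),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca> %d components over %d variables\n",
              x$n_components, nrow(x$loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_var_pct), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.spectra_pca <- function(object, ...) {
  df <- data.frame(component = seq_along(object$all_var_pct),
                   var_pct = object$all_var_pct,
                   cum_var_pct = cumsum(object$all_var_pct))
  class(df) <- c("summary.spectra_pca", "data.frame")
  df
}

#' @export
predict.spectra_pca <- function(object, newdata, ...) {
  X <- set_to_matrix(newdata)
  sweep(X, 2, object$mean) %*% object$loadings
}

#' @export
plot.spectra_pca <- function(x, components = c(1, 2), labels = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  plot(s[, 1], s[, 2],
       xlab = sprintf("PC%d (%.1f%%)", components[1],
                      x$explained_var_pct[components[1]]),
       ylab = sprintf("PC%d (%.1f%%)", components[2],
                      x$explained_var_pct[components[2]]),
       col = if (is.null(labels)) 1 else as.integer(factor(labels)), ...)
  invisible(x)
}

#' Per-region explained-variance comparison
#'
#' Fits one PCA per spectral region to identically preprocessed data and
#' tabulates the per-component explained variance, the screening step used
#' to choose the modelling region.
#'
#' @param set A [spectrum_set()].
#' @param regions Named list of [region_spec()] objects.
#' @param n_components Components to tabulate per region.
#' @return A `data.frame` with columns `region`, `component`, `var_pct`.
#' @export
explained_variance_profile <- function(set, regions, n_components = 3) {
  stopifnot(inherits(set, "spectrum_set"), length(regions) >= 1)
  if (is.null(names(regions)))
    names(regions) <- vapply(regions, format, character(1))
  rows <- lapply(names(regions), function(nm) {
    fit <- pca_fit(crop_region(set, regions[[nm]]), n_components)
    data.frame(region = nm, component = seq_len(n_components),
               var_pct = fit$explained_var_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select influential wavenumbers from PCA loadings
#'
#' Combines the first (up to) three components' absolute loadings,
#' weighted by explained variance, and greedily picks local maxima of the
#' combined magnitude, enforcing a minimum separation between picks. Ties
#' break toward the higher wavenumber.
#'
#' @param fit A [pca_fit()] result.
#' @param k Number of wavenumbers to select.
#' @param min_separation Minimum distance between picks, cm-1 (default 10).
#' @param grid Wavenumber vector matching the loading rows; defaults to
#'   the grid stored in `fit`.
#' @return An object of class `"selected_wavenumbers"`: fields
#'   `wavenumbers` and `scores` (combined |loading| magnitude), sorted by
#'   decreasing magnitude.
#' @export
select_wavenumbers_from_loadings <- function(fit, k, min_separation = 10,
                                             grid = fit$wavenumbers) {
  stopifnot(inherits(fit, "spectra_pca"), k >= 1)
  if (is.null(grid)) stop("a wavenumber grid is required")
  if (length(grid) != nrow(fit$loadings))
    stop("grid length does not match the loading rows")
  m <- min(3, fit$n_components)
  w <- fit$explained_var_pct[seq_len(m)] / 100
  combined <- abs(fit$loadings[, seq_len(m), drop = FALSE]) %*% w
  combined <- as.numeric(combined)
  n <- length(combined)
  # local maxima on the stored (descending-wavenumber) axis; >= on the
  # high-wavenumber side breaks plateau ties toward higher wavenumber
  is_max <- c(combined[1] >= combined[2],
              combined[2:(n - 1)] > combined[1:(n - 2)] &
                combined[2:(n - 1)] >= combined[3:n],
              combined[n] > combined[n - 1])
  cand <- which(is_max)
  cand <- cand[order(-combined[cand], -grid[cand])]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) == k) break
    if (all(abs(grid[i] - grid[picked]) >= min_separation))
      picked <- c(picked, i)
  }
  if (length(picked) < k)
    stop(sprintf(paste0("only %d separated loading maxima found (need %d); ",
                        "peaks at: %s"),
                 length(picked), k,
                 paste(round(grid[picked], 1), collapse = ", ")))
  structure(list(wavenumbers = grid[picked], scores = combined[picked]),
            class = "selected_wavenumbers")
}

#' @export
print.selected_wavenumbers <- function(x, ...) {
  cat("<selected_wavenumbers>",
      paste(sprintf("%g", x$wavenumbers), collapse = ", "), "cm-1\n")
  invisible(x)
}
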