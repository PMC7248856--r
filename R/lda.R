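# Fisher linear discriminant analysis ------------------------------------

#' Extract a feature table from a spectrum set at chosen wavenumbers
#'
#' Takes the absorbance at the grid point nearest each requested
#' wavenumber (the 2 cm-1 grid never places a band center more than one
#' point away).
#'
#' @param set A [spectrum_set()] (typically smoothed, non-derivative).
#' @param wavenumbers Wavenumbers (cm-1) to sample, e.g.
#'   [lda_marker_wavenumbers].
#' @param labels Group label per spectrum; defaults to
#'   [blend_group_labels()] of the set metadata.
#' @return A list of class `"feature_table"`: numeric matrix `x`
#'   (samples x wavenumbers) and factor `labels`.
#' @export
extract_features <- function(set, wavenumbers = lda_marker_wavenumbers,
                             labels = blend_group_labels(set$meta)) {
  stopifnot(inherits(set, "spectrum_set"))
  idx <- nearest_index(set$wavenumbers, wavenumbers)
  x <- t(set$absorbance[idx, , drop = FALSE])
  colnames(x) <- sprintf("wn%g", wavenumbers)
  rownames(x) <- set$meta$sample_id
  feature_table(x, labels)
}

#' Assemble a feature table from a matrix and group labels
#'
#' @param x Numeric samples-by-variables matrix without missing values.
#' @param labels Group label per row; at least 2 groups, each of size >= 2.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(x, labels) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("feature table contains missing values")
  labels <- factor(labels, levels = sort(unique(as.character(labels))))
  if (nrow(x) != length(labels)) stop("one label per row required")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("at least 2 groups required")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  structure(list(x = x, labels = labels), class = "feature_table")
}

#' Fit a linear discriminant model
#'
#' Pooled within-class covariance `sum((n_g - 1) S_g) / (n - G)`, equal
#' priors, and classification by the nearest class mean in the Mahalanobis
#' metric of the pooled covariance. Canonical axes come from the
#' generalized eigenproblem of between-class scatter against the pooled
#' covariance, ordered by eigenvalue. When the pooled covariance is
#' numerically singular (condition number > 1e10) an optional ridge
#' `lambda I` with `lambda = 1e-8 trace/p` is applied.
#'
#' @param features A [feature_table()].
#' @param regularize Apply the ridge automatically when needed
#'   (default TRUE; with FALSE a singular pooled covariance errors).
#' @return An object of class `"oil_lda"`.
#' @export
lda_fit <- function(features, regularize = TRUE) {
  stopifnot(inherits(features, "feature_table"))
  x <- features$x; labels <- features$labels
  n <- nrow(x); p <- ncol(x)
  groups <- levels(labels)
  G <- length(groups)
  if (n <= G) stop("need more samples than groups")
  means <- matrix(0, G, p, dimnames = list(groups, colnames(x)))
  for (g in groups) means[g, ] <- colMeans(x[labels == g, , drop = FALSE])
  Sw <- matrix(0, p, p)
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  Sw <- Sw / (n - G)
  ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
    if (!regularize)
      stop("pooled within-class covariance is numerically singular; ",
           "consider regularize = TRUE")
    Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / p, p)
  }
  grand <- colMeans(x)
  Sb <- matrix(0, p, p)
  for (g in groups) {
    ng <- sum(labels == g)
    d <- means[g, ] - grand
    Sb <- Sb + ng * tcrossprod(d)
  }
  Sb <- Sb / (n - 1)
  # canonical axes via whitening: Sw^{-1/2} applied to Sb
  Ch <- chol(Sw)
  W <- backsolve(Ch, diag(p), transpose = TRUE)  # W' W = Sw^{-1}
  M <- W %*% Sb %*% t(W)
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  r <- min(G - 1, p)
  axes <- t(W) %*% ed$vectors[, seq_len(r), drop = FALSE]
  colnames(axes) <- paste0("DF", seq_len(r))
  structure(list(class_means = means, pooled_cov = Sw,
                 priors = stats::setNames(rep(1 / G, G), groups),
                 discriminant_axes = axes,
                 eigenvalues = ed$values[seq_len(r)],
                 grand_mean = grand, groups = groups,
                 variables = colnames(x)),
            class = "oil_lda")
}

#' @export
print.oil_lda <- function(x, ...) {
  cat(sprintf("<oil_lda> %d groups, %d variables\n",
              length(x$groups), ncol(x$class_means)))
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  discriminant eigenvalues:",
      paste(sprintf("%.3g", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

mahalanobis_to_means <- function(model, x) {
  Ch <- chol(model$pooled_cov)
  d2 <- vapply(model$groups, function(g) {
    diff <- sweep(x, 2, model$class_means[g, ])
    z <- diff %*% backsolve(Ch, diag(ncol(x)))
    rowSums(z^2)
  }, numeric(nrow(x)))
  matrix(d2, nrow = nrow(x), dimnames = list(rownames(x), model$groups))
}

#' Classify samples with a fitted LDA model
#'
#' Assigns each sample to the class mean with the smallest Mahalanobis
#' distance (equal priors); exact distance ties break toward the
#' lexicographically first group label. Canonical scores on the first two
#' discriminant axes are returned for plotting.
#'
#' @param object An [lda_fit()] model.
#' @param newdata A [feature_table()], numeric matrix, or
#'   [spectrum_set()] features with matching variables.
#' @param ... Unused.
#' @return A list with `labels` (factor), `scores` (first two canonical
#'   factors), and the full distance matrix `d2`.
#' @export
predict.oil_lda <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  if (ncol(x) != ncol(object$class_means))
    stop("feature dimension does not match the fitted model")
  d2 <- mahalanobis_to_means(object, x)
  # columns are in sorted (lexicographic) group order, so the first
  # minimum is the lexicographically first label on ties
  pred <- object$groups[apply(d2, 1, which.min)]
  nf <- min(2, ncol(object$discriminant_axes))
  scores <- sweep(x, 2, object$grand_mean) %*%
    object$discriminant_axes[, seq_len(nf), drop = FALSE]
  list(labels = factor(pred, levels = object$groups), scores = scores, d2 = d2)
}

confusion_matrix <- function(truth, pred, groups) {
  truth <- factor(truth, levels = groups)
  pred <- factor(pred, levels = groups)
  counts <- table(truth = truth, predicted = pred)
  percent <- 100 * prop.table(counts, 1)
  structure(list(counts = unclass(counts), percent = unclass(percent),
                 accuracy_pct = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> overall %.2f%% correct\n", x$accuracy_pct))
  print(x$counts)
  invisible(x)
}

#' Leave-one-out cross-validated LDA classification
#'
#' For each sample the model is refitted on the remaining `n - 1` samples
#' and the held-out sample is classified; entirely deterministic. Both the
#' cross-validated and the resubstitution confusion matrices are returned.
#'
#' @param features A [feature_table()] with every group of size >= 3.
#' @param regularize Passed to [lda_fit()].
#' @return A list of class `"lda_cv"`: `cv` and `resubstitution` confusion
#'   matrices (counts, row percent, overall accuracy) and the per-sample
#'   `cv_labels`.
#' @export
loo_cross_validate <- function(features, regularize = TRUE) {
  stopifnot(inherits(features, "feature_table"))
  sizes <- table(features$labels)
  if (any(sizes < 3))
    stop("leave-one-out needs every group size >= 3")
  n <- nrow(features$x)
  groups <- levels(features$labels)
  full <- lda_fit(features, regularize)
  resub_pred <- predict(full, features)$labels
  cv_pred <- character(n)
  for (i in seq_len(n)) {
    ft <- feature_table(features$x[-i, , drop = FALSE], features$labels[-i])
    fit <- lda_fit(ft, regularize)
    cv_pred[i] <- as.character(
      predict(fit, features$x[i, , drop = FALSE])$labels)
  }
  structure(list(
    cv = confusion_matrix(features$labels, cv_pred, groups),
    resubstitution = confusion_matrix(features$labels, resub_pred, groups),
    cv_labels = factor(cv_pred, levels = groups)),
    class = "lda_cv")
}

#' @export
print.lda_cv <- function(x, ...) {
  cat(sprintf("LOO cross-validated: %.2f%% correct | resubstitution: %.2f%%\n",
              x$cv$accuracy_pct, x$resubstitution$accuracy_pct))
  print(x$cv$counts)
  invisible(x)
}
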