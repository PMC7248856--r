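# I1119/I1096 band-ratio purity screen -----------------------------------

PURITY_THRESHOLD <- 1.000
LABEL_PURE <- "pure-CAO-consistent"
LABEL_SUSPECT <- "non-CAO-or-adulterated"

#' Windowed peak height
#'
#' Maximum absorbance over grid points within `center +/- half_window`
#' cm-1 -- absolute height above zero, with no local baseline anchoring.
#' The windowed maximum makes the measurement robust to a band apex
#' sitting a grid point or two off its nominal center.
#'
#' @param x A `spectrum`.
#' @param center Nominal band position, cm-1.
#' @param half_window Half-width of the search window, cm-1 (default 4).
#' @return Peak height in AU.
#' @export
peak_height <- function(x, center, half_window = 4) {
  stopifnot(inherits(x, "spectrum"))
  idx <- which(abs(x$wavenumbers - center) <= half_window)
  if (!length(idx))
    stop(sprintf("no grid points within %g +/- %g cm-1", center, half_window))
  max(x$absorbance[idx])
}

#' Ester C-O band intensity ratio of one spectrum
#'
#' `ratio = peak_height(1119) / peak_height(1096)`; a strict ratio > 1.000
#' is consistent with pure camellia oil, anything at or below the threshold
#' (including exactly 1.000) is flagged.
#'
#' @param x A `spectrum` covering 1092-1123 cm-1.
#' @param half_window Peak search half-window in cm-1.
#' @return A list of class `"ratio_result"` with fields `i1119`, `i1096`,
#'   `ratio` and `label`.
#' @export
intensity_ratio <- function(x, half_window = 4) {
  stopifnot(inherits(x, "spectrum"))
  rng <- range(x$wavenumbers)
  if (rng[1] > 1096 - half_window || rng[2] < 1119 + half_window)
    stop("spectrum must cover the 1092-1123 cm-1 region")
  i1119 <- peak_height(x, 1119, half_window)
  i1096 <- peak_height(x, 1096, half_window)
  if (i1096 <= 0)
    stop("non-positive 1096 cm-1 peak height; cannot form a ratio")
  ratio <- i1119 / i1096
  structure(list(i1119 = i1119, i1096 = i1096, ratio = ratio,
                 label = if (ratio > PURITY_THRESHOLD) LABEL_PURE else LABEL_SUSPECT),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("I1119 = %.5f AU, I1096 = %.5f AU, ratio = %.4f -> %s\n",
              x$i1119, x$i1096, x$ratio, x$label))
  invisible(x)
}

#' Ratio table for a spectrum set
#'
#' One row per spectrum, ordered by `sample_id`.
#'
#' @param set A [spectrum_set()] (typically smoothed, non-derivative).
#' @param half_window Peak search half-window in cm-1.
#' @return A `data.frame` with columns `sample_id`, `oil_type`,
#'   `blend_fraction_v`, `i1119`, `i1096`, `ratio`, `label`.
#' @export
ratio_table <- function(set, half_window = 4) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!length(set)) stop("ratio_table needs a non-empty spectrum set")
  rows <- lapply(seq_len(length(set)), function(i) {
    r <- intensity_ratio(set[[i]], half_window)
    data.frame(sample_id = set$meta$sample_id[i],
               oil_type = set$meta$oil_type[i],
               blend_fraction_v = set$meta$blend_fraction_v[i],
               i1119 = r$i1119, i1096 = r$i1096, ratio = r$ratio,
               label = r$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smallest tabulated blend level at or below the purity threshold
#'
#' For a blend ladder (one base/adulterant pair measured at several
#' levels), returns the smallest tabulated level whose I1119/I1096 ratio
#' is <= 1.000.
#'
#' @param series A [ratio_table()] restricted to one blend ladder; must
#'   contain at least two levels and span the threshold.
#' @return The crossover level in % v/v.
#' @export
crossover_level <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("blend_fraction_v", "ratio") %in% names(series)))
  agg <- stats::aggregate(ratio ~ blend_fraction_v, series, mean)
  agg <- agg[order(agg$blend_fraction_v), ]
  if (nrow(agg) < 2)
    stop("crossover_level needs at least two blend levels")
  below <- agg$ratio <= PURITY_THRESHOLD
  if (!any(below))
    stop(sprintf(paste0("no tabulated level crosses the %.3f threshold ",
                        "(minimum ratio %.4f at %g%% v/v)"),
                 PURITY_THRESHOLD, min(agg$ratio),
                 agg$blend_fraction_v[which.min(agg$ratio)]))
  agg$blend_fraction_v[which(below)[1]]
}
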