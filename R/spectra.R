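# Spectrum and spectrum_set containers -----------------------------------

OIL_TYPES <- c("CAO", "RSO", "SBO", "CO", "SFO", "PO", "SO", "BLEND")

#' Construct per-sample metadata
#'
#' @param sample_id Sample identifier (unique within a set).
#' @param oil_type One of `"CAO"`, `"RSO"`, `"SBO"`, `"CO"`, `"SFO"`,
#'   `"PO"`, `"SO"`, `"BLEND"`.
#' @param blend_fraction_v Adulterant volume fraction in percent v/v,
#'   in `[0, 100]`. `0` for a pure base oil, `100` for the pure adulterant;
#'   `oil_type` must be `"BLEND"` exactly when the fraction is strictly
#'   between 0 and 100.
#' @param base_brand,adulterant_brand Brand labels ("" when not applicable).
#' @param replicate Positive integer replicate index.
#' @return A one-row `data.frame` with the six metadata fields.
#' @export
sample_meta <- function(sample_id, oil_type, blend_fraction_v = 0,
                        base_brand = "", adulterant_brand = "",
                        replicate = 1L) {
  meta <- data.frame(
    sample_id = as.character(sample_id),
    oil_type = as.character(oil_type),
    blend_fraction_v = as.numeric(blend_fraction_v),
    base_brand = as.character(base_brand),
    adulterant_brand = as.character(adulterant_brand),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_meta(meta)
  meta
}

validate_meta <- function(meta) {
  required <- c("sample_id", "oil_type", "blend_fraction_v",
                "base_brand", "adulterant_brand", "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing field(s): ", paste(missing, collapse = ", "))
  bad <- !meta$oil_type %in% OIL_TYPES
  if (any(bad))
    stop("unknown oil_type: ", paste(unique(meta$oil_type[bad]), collapse = ", "))
  v <- meta$blend_fraction_v
  if (any(!is.finite(v)) || any(v < 0 | v > 100))
    stop("blend_fraction_v must lie in [0, 100]")
  mid <- v > 0 & v < 100
  if (any(mid & meta$oil_type != "BLEND") || any(!mid & meta$oil_type == "BLEND"))
    stop("oil_type must be \"BLEND\" exactly when 0 < blend_fraction_v < 100")
  if (any(meta$replicate < 1))
    stop("replicate must be a positive integer")
  invisible(meta)
}

#' Construct a single absorbance spectrum
#'
#' Wavenumbers are stored high-to-low (4000 -> 650 cm-1, the spectrometer
#' presentation order); an ascending input grid is reversed on construction.
#'
#' @param wavenumbers Strictly monotonic numeric vector of wavenumbers
#'   (cm-1), length >= 2.
#' @param absorbance Finite numeric vector of absorbances (AU), same length.
#' @param meta One-row metadata `data.frame`, see [sample_meta()].
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumbers, absorbance, meta = sample_meta("s1", "CAO")) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2)
    stop("a spectrum needs at least 2 points")
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length")
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d < 0)) {
    stop("wavenumbers must be strictly monotonic")
  }
  if (!all(is.finite(absorbance)))
    stop("absorbance values must be finite")
  validate_meta(meta)
  if (nrow(meta) != 1) stop("meta must have exactly one row")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s (%s), %d points, %.0f-%.0f cm-1\n",
              x$meta$sample_id, x$meta$oil_type, length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  plot(x$wavenumbers, x$absorbance, type = "l", xlim = rev(range(x$wavenumbers)),
       xlab = expression(Wavenumber ~ (cm^-1)), ylab = "Absorbance (AU)", ...)
  invisible(x)
}

#' Bundle spectra sharing one wavenumber grid
#'
#' @param spectra A list of [spectrum()] objects with bitwise-identical
#'   wavenumber grids.
#' @return An object of class `"spectrum_set"`: the shared grid, a
#'   points-by-samples absorbance matrix, and a metadata `data.frame`
#'   with one row per sample.
#' @export
spectrum_set <- function(spectra) {
  if (!length(spectra)) stop("spectrum_set needs at least one spectrum")
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("all elements must be spectrum objects")
  grid <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (!identical(s$wavenumbers, grid))
      stop("all spectra in a set must share an identical wavenumber grid (sample ",
           s$meta$sample_id, " differs)")
  }
  abs_mat <- vapply(spectra, function(s) s$absorbance, numeric(length(grid)))
  meta <- do.call(rbind, lapply(spectra, function(s) s$meta))
  rownames(meta) <- NULL
  colnames(abs_mat) <- meta$sample_id
  new_spectrum_set(grid, abs_mat, meta)
}

new_spectrum_set <- function(wavenumbers, absorbance, meta) {
  validate_meta(meta)
  stopifnot(nrow(absorbance) == length(wavenumbers),
            ncol(absorbance) == nrow(meta))
  structure(list(wavenumbers = wavenumbers,
                 absorbance = absorbance,
                 meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, %d points, %.0f-%.0f cm-1\n",
              ncol(x$absorbance), length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers)))
  tab <- table(x$meta$oil_type)
  cat("  oil types:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) ncol(x$absorbance)

#' @export
`[.spectrum_set` <- function(x, i) {
  new_spectrum_set(x$wavenumbers, x$absorbance[, i, drop = FALSE],
                   x$meta[i, , drop = FALSE])
}

#' @export
`[[.spectrum_set` <- function(x, i) {
  spectrum(x$wavenumbers, x$absorbance[, i], x$meta[i, , drop = FALSE])
}

#' @export
plot.spectrum_set <- function(x, ...) {
  matplot(x$wavenumbers, x$absorbance, type = "l", lty = 1,
          xlim = rev(range(x$wavenumbers)),
          xlab = expression(Wavenumber ~ (cm^-1)), ylab = "Absorbance (AU)", ...)
  invisible(x)
}

#' @export
as.data.frame.spectrum_set <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, x$absorbance, check.names = FALSE)
}

# Region handling ---------------------------------------------------------

#' Define spectral windows in cm-1
#'
#' @param high,low Numeric vectors of equal length: each window spans
#'   `[low[i], high[i]]`, both endpoints inclusive. Windows must not overlap.
#' @return An object of class `"region_spec"`.
#' @examples
#' region_spec(1800, 650)
#' region_spec(c(3050, 1800), c(2750, 650))
#' @export
region_spec <- function(high, low) {
  if (length(high) != length(low) || !length(high))
    stop("high and low must be non-empty vectors of equal length")
  if (any(high <= low)) stop("each window needs high > low")
  o <- order(high, decreasing = TRUE)
  high <- high[o]; low <- low[o]
  if (length(high) > 1 && any(low[-length(low)] <= high[-1]))
    stop("windows must not overlap")
  structure(list(high = high, low = low), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>", paste(sprintf("%g-%g", x$high, x$low), collapse = ", "),
      "cm-1\n")
  invisible(x)
}

#' @export
format.region_spec <- function(x, ...) {
  paste(sprintf("%g-%g", x$high, x$low), collapse = ",")
}

region_indices <- function(grid, region) {
  stopifnot(inherits(region, "region_spec"))
  keep <- rep(FALSE, length(grid))
  for (i in seq_along(region$high)) {
    inw <- grid >= region$low[i] & grid <= region$high[i]
    if (!any(inw))
      stop(sprintf("window %g-%g cm-1 lies fully outside the grid",
                   region$high[i], region$low[i]))
    keep <- keep | inw
  }
  which(keep)
}

#' Restrict a spectrum or set to spectral windows
#'
#' Keeps grid points whose wavenumber falls inside any window (endpoints
#' inclusive); storage order and metadata are unchanged.
#'
#' @param x A `spectrum` or `spectrum_set`.
#' @param region A [region_spec()].
#' @return Object of the same class on the reduced grid.
#' @export
crop_region <- function(x, region) UseMethod("crop_region")

#' @export
crop_region.spectrum <- function(x, region) {
  idx <- region_indices(x$wavenumbers, region)
  spectrum(x$wavenumbers[idx], x$absorbance[idx], x$meta)
}

#' @export
crop_region.spectrum_set <- function(x, region) {
  idx <- region_indices(x$wavenumbers, region)
  new_spectrum_set(x$wavenumbers[idx], x$absorbance[idx, , drop = FALSE], x$meta)
}
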