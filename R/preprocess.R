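# Savitzky-Golay preprocessing -------------------------------------------

check_sg_args <- function(n_points, window, polyorder) {
  if (window %% 2 != 1 || window < 3)
    stop("sg window must be an odd integer >= 3")
  if (polyorder < 0 || polyorder >= window)
    stop("sg polyorder must satisfy 0 <= polyorder < window")
  if (n_points < window)
    stop("spectrum shorter than the filter window")
  invisible(NULL)
}

apply_sg <- function(abs_mat, wavenumbers, window, polyorder, deriv = 0) {
  check_sg_args(nrow(abs_mat), window, polyorder)
  ts <- 1
  if (deriv > 0) {
    steps <- diff(wavenumbers)
    if (max(abs(steps - steps[1])) > 1e-8 * abs(steps[1]))
      stop("derivative filtering requires a uniform wavenumber grid")
    ts <- abs(steps[1])
  }
  # stored high-to-low; filter on the ascending view so d/d(nu) has the
  # conventional sign, then restore storage order
  idx <- rev(seq_len(nrow(abs_mat)))
  out <- apply(abs_mat[idx, , drop = FALSE], 2, function(y)
    as.numeric(signal::sgolayfilt(y, p = polyorder, n = window, m = deriv,
                                  ts = ts)))
  out <- matrix(out, nrow = nrow(abs_mat))[idx, , drop = FALSE]
  dimnames(out) <- dimnames(abs_mat)
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; the terminal polynomial fits
#' supply the edge values, and the grid is unchanged. Exact for inputs
#' that are polynomials of degree <= `polyorder`.
#'
#' @param x A `spectrum` or `spectrum_set`.
#' @param window Odd window length in points (>= 3).
#' @param polyorder Polynomial order, < `window`.
#' @return Object of the same class.
#' @export
savgol_smooth <- function(x, window = 11, polyorder = 2) UseMethod("savgol_smooth")

#' @export
savgol_smooth.spectrum <- function(x, window = 11, polyorder = 2) {
  ab <- apply_sg(matrix(x$absorbance, ncol = 1), x$wavenumbers, window, polyorder)
  spectrum(x$wavenumbers, ab[, 1], x$meta)
}

#' @export
savgol_smooth.spectrum_set <- function(x, window = 11, polyorder = 2) {
  new_spectrum_set(x$wavenumbers,
                   apply_sg(x$absorbance, x$wavenumbers, window, polyorder),
                   x$meta)
}

#' Savitzky-Golay first derivative
#'
#' First derivative of absorbance with respect to wavenumber (AU per cm-1),
#' with the sign convention of the ascending wavenumber axis. Exact for
#' polynomials of degree <= `polyorder`; removes any additive constant
#' baseline exactly.
#'
#' @inheritParams savgol_smooth
#' @export
first_derivative <- function(x, window = 11, polyorder = 3) UseMethod("first_derivative")

#' @export
first_derivative.spectrum <- function(x, window = 11, polyorder = 3) {
  ab <- apply_sg(matrix(x$absorbance, ncol = 1), x$wavenumbers, window,
                 polyorder, deriv = 1)
  spectrum(x$wavenumbers, ab[, 1], x$meta)
}

#' @export
first_derivative.spectrum_set <- function(x, window = 11, polyorder = 3) {
  new_spectrum_set(x$wavenumbers,
                   apply_sg(x$absorbance, x$wavenumbers, window, polyorder,
                            deriv = 1),
                   x$meta)
}

#' Preprocessing configuration
#'
#' @param sg_window Odd smoothing window in points; `1` disables smoothing.
#' @param sg_polyorder Smoothing polynomial order.
#' @param derivative_order 0 (smoothing only) or 1 (first derivative).
#' @param derivative_polyorder Polynomial order of the derivative filter.
#' @param region A [region_spec()] to crop to after filtering.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(sg_window = 11, sg_polyorder = 2,
                              derivative_order = 1, derivative_polyorder = 3,
                              region = region_spec(1800, 650)) {
  stopifnot(derivative_order %in% c(0, 1), inherits(region, "region_spec"))
  if (sg_window != 1) {
    if (sg_window %% 2 != 1) stop("sg_window must be odd")
    if (sg_window < sg_polyorder + 2)
      stop("sg_window must be >= sg_polyorder + 2")
  }
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 derivative_order = derivative_order,
                 derivative_polyorder = derivative_polyorder,
                 region = region),
            class = "preprocess_config")
}

#' Apply the standard preprocessing chain to a spectrum set
#'
#' Smooth, then differentiate (if `derivative_order` is 1), then crop to
#' the modelling region -- in that fixed order, so cropping never exposes
#' filter edge effects inside the region. Metadata is preserved.
#'
#' @param set A [spectrum_set()].
#' @param cfg A [preprocess_config()].
#' @return A [spectrum_set()].
#' @export
preprocess_set <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"), inherits(cfg, "preprocess_config"))
  out <- set
  if (cfg$sg_window > 1)
    out <- savgol_smooth(out, cfg$sg_window, cfg$sg_polyorder)
  if (cfg$derivative_order == 1)
    out <- first_derivative(out, max(cfg$sg_window, 3), cfg$derivative_polyorder)
  crop_region(out, cfg$region)
}
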