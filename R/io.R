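# CSV and JCAMP-DX readers/writers ---------------------------------------

meta_path_for <- function(path) {
  sub("(\\.[^.]+)?$", "_meta\\1", path)
}

#' Write a spectrum set to wide CSV plus a metadata sidecar
#'
#' The CSV holds the wavenumber grid in the first column and one sample per
#' remaining column (full decimal precision, dot decimal separator, header
#' row). Metadata goes to a sidecar CSV at the same path with a `_meta`
#' suffix before the extension.
#'
#' @param set A [spectrum_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  if (!inherits(set, "spectrum_set")) stop("set must be a spectrum_set")
  if (!length(set)) stop("cannot write an empty spectrum set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("wavenumber", set$meta$sample_id), collapse = ","), con)
  body <- apply(cbind(set$wavenumbers, set$absorbance), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = ","))
  writeLines(body, con)
  write.csv(set$meta, meta_path_for(path), row.names = FALSE)
  invisible(path)
}

#' Read a spectrum set from wide CSV plus its metadata sidecar
#'
#' Inverse of [write_spectra_csv()]: expects wavenumber in the first
#' column, one sample per remaining column, and a `_meta` sidecar whose
#' `sample_id` values match the column names.
#'
#' @param path CSV path.
#' @return A [spectrum_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "numeric")
  if (ncol(df) < 2) stop("expected a wavenumber column plus at least one sample")
  grid <- df[[1]]
  d <- diff(grid)
  if (!(all(d > 0) || all(d < 0)))
    stop("non-monotonic wavenumber grid in ", path)
  mpath <- meta_path_for(path)
  if (!file.exists(mpath)) stop("missing metadata sidecar: ", mpath)
  meta <- read.csv(mpath, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  base_brand = "character",
                                  adulterant_brand = "character"))
  meta$blend_fraction_v <- as.numeric(meta$blend_fraction_v)
  meta$replicate <- as.integer(meta$replicate)
  meta$base_brand[is.na(meta$base_brand)] <- ""
  meta$adulterant_brand[is.na(meta$adulterant_brand)] <- ""
  ids <- names(df)[-1]
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss))
    stop("no metadata row for sample(s): ", paste(miss, collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  abs_mat <- as.matrix(df[-1])
  if (all(d > 0)) {
    grid <- rev(grid)
    abs_mat <- abs_mat[rev(seq_along(grid)), , drop = FALSE]
  }
  new_spectrum_set(grid, abs_mat, meta)
}

#' Read a fixed-step JCAMP-DX spectrum
#'
#' Minimal reader for single-block JCAMP-DX files whose data section is an
#' `XYDATA=(X++(Y..Y))` table with a fixed abscissa step (the common export
#' of FTIR vendor software). Y values are scaled by `YFACTOR` when present.
#'
#' @param path JCAMP-DX file path.
#' @param meta Optional [sample_meta()] row; defaults to the `##TITLE`.
#' @return A [spectrum()].
#' @export
read_jcamp <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "\\s*="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]+=", "", hit[[1]]))
  }
  start <- grep("^##XYDATA\\s*=\\s*\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop("no XYDATA=(X++(Y..Y)) block in ", path)
  end <- grep("^##END", lines)
  end <- end[end > start[1]]
  if (!length(end)) end <- length(lines) + 1
  body <- lines[(start[1] + 1):(end[1] - 1)]
  body <- body[nzchar(trimws(body))]
  yfactor <- as.numeric(get_field("YFACTOR") %||% "1")
  rows <- lapply(body, function(ln) as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
  firstx <- vapply(rows, `[`, numeric(1), 1)
  npts_row <- vapply(rows, length, integer(1)) - 1L
  step_hdr <- get_field("DELTAX")
  if (!is.null(step_hdr)) {
    step <- as.numeric(step_hdr)
  } else {
    # infer the step from consecutive row start values
    if (length(rows) < 2) stop("cannot infer DELTAX from a single data line")
    step <- (firstx[2] - firstx[1]) / npts_row[1]
  }
  x <- unlist(lapply(seq_along(rows), function(i)
    firstx[i] + step * (seq_len(npts_row[i]) - 1)))
  y <- unlist(lapply(rows, function(r) r[-1])) * yfactor
  if (is.null(meta)) {
    title <- get_field("TITLE") %||% basename(path)
    meta <- sample_meta(title, "CAO")
  }
  spectrum(x, y, meta)
}
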