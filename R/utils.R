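# internal helpers shared across modules

#' Derive a deterministic 31-bit seed from a base seed and string labels
#'
#' Used so every stochastic draw in the generator is keyed to
#' (seed, oil, brand, replicate, ...) and nothing depends on R's global
#' RNG state between calls.
#' @noRd
derive_seed <- function(seed, ...) {
  s <- paste(c(format(seed), ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed, restoring global state after
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Index of grid point nearest to each target wavenumber
#' @noRd
nearest_index <- function(grid, targets) {
  vapply(targets, function(w) which.min(abs(grid - w)), integer(1))
}

#' FNV-1a hash of an R object's serialized bytes, as hex
#'
#' Small and dependency-free; used to stamp pipeline outputs with a
#' configuration fingerprint.
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialization header (R version stamp) so the hash depends on
  # content only
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
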