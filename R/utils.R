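# Read/write helpers: all on-disk tables are plain TSV.
read_tsv_file <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed is fanned out to per-stage seeds by a fixed affine map so
#' that individual stages are reproducible in isolation. Results stay below
#' 2^31.
#'
#' @param seed integer global seed.
#' @param k integer stage index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  as.integer((abs(as.numeric(seed)) %% 1048573) * 1024 + (k %% 1024))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vapply shorthands
vnum <- function(x, f, ...) vapply(x, f, numeric(1), ...)
vchr <- function(x, f, ...) vapply(x, f, character(1), ...)

assert_range <- function(r, name) {
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
    stop(sprintf("configuration error: '%s' must be a (min, max) interval with min <= max", name),
         call. = FALSE)
  }
  invisible(r)
}

assert_frac <- function(x, name) {
  if (any(x < 0 | x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
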