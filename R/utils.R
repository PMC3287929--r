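# Internal helpers: seed stream-splitting, validation, light logging.

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' All randomness in the pipeline flows from one master seed; independent
#' substreams for each (stage, stratum, bin, replicate, ...) are derived by
#' hashing a string key together with the master seed. This keeps results
#' identical regardless of evaluation order and lets the observed and null
#' stage-1 runs share rare-SNP samples while using distinct permutation
#' streams.
#'
#' Arithmetic stays below 2^53 so the modular reduction is exact in doubles;
#' the result is a strictly positive 32-bit integer.
#'
#' @param seed master seed (integer-valued scalar).
#' @param ... key components, coerced to character and joined with "/".
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "stage1", "pop1", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(c(...), collapse = "/")
  p <- 2147483647
  h <- as.double(seed) %% p
  h <- (h * 69069) %% p
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% p
  h <- as.integer(h)
  if (h == 0L) 1L else h
}

# run a block with a temporary RNG seed, restoring prior state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rt_log <- function(fmt, ..., verbose = getOption("raretag.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

# write a TSV deterministically (no quoting surprises, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
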