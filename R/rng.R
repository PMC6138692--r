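#' Derive a reproducible substream seed
#'
#' All stochastic stages draw their randomness from a single master seed via
#' named substreams, so any stage can be regenerated independently of the
#' others.  The substream seed is a deterministic hash of the master seed and
#' the stream name, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed master seed (single integer).
#' @param stream character stream name, e.g. `"common_variants"`.
#' @return an integer seed.
#' @export
#' @examples
#' substream_seed(1L, "rare_variants")
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream),
            length(stream) == 1L, nzchar(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483629
  # multiplicative mixing so distinct master seeds give unrelated streams
  s <- abs(as.numeric(seed)) %% 2147483629
  as.integer((s * 48271 + h * 16807 + 1) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' simulation helpers do not perturb the global random stream.  A `NULL` seed
#' evaluates `code` with the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
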