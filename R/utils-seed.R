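#' @keywords internal
#' Stable 31-bit polynomial hash of a character string.
#'
#' Used to derive per-pair random substreams from a single root seed, so that
#' pairwise null models give identical results whether pairs are processed
#' serially, in a different order, or one at a time.
hash_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 0
  for (code in utf8ToInt(s)) {
    # products stay below 2^53, so double arithmetic is exact
    h <- (h * 31 + code) %% 2147483647
  }
  h
}

#' @keywords internal
#' Derive a deterministic substream seed from a root seed and string labels.
pair_seed <- function(root_seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  as.integer((as.numeric(root_seed) + hash_string(labels)) %% 2147483647)
}

#' @keywords internal
#' Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
#' A NULL seed leaves the current RNG stream untouched (and consumed).
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
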