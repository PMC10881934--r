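# Internal helpers shared across modules.

MEF <- "MEf"
BEF <- "BEf"
MODEL_KINDS <- c(MEF, BEF)

#' @keywords internal
match_kind <- function(kind) {
  if (length(kind) != 1L || !kind %in% MODEL_KINDS) {
    stop("`kind` must be one of \"MEf\" or \"BEf\", got: ",
         paste(kind, collapse = ", "), call. = FALSE)
  }
  kind
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic sub-seed for one (master seed, integer key) pair, kept inside
# the 32-bit integer range. Used to give each dataset / training run of an
# experiment its own documented stream.
derive_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(key) * 104729) %% 2147483587L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
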