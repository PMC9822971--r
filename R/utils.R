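## internal validation + RNG helpers

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("rfdseg_validation_error", "error")))
}

stop_structural <- function(...) {
  stop(errorCondition(paste0(...), class = c("rfdseg_structural_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

## Derive a per-stage child seed from a global seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
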