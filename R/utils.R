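# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage child seed derived from the run seed, so that a
# stage rerun in isolation draws the same stream as inside the full run.
# Kept strictly below 2^31 - 1.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((as.numeric(seed) * 7919 + h * 12347) %% 2147483646 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x %in% c(0, 1))
}

# Column standard deviations with the n-1 denominator.
col_sds <- function(x) apply(x, 2L, stats::sd)
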