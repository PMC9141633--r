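# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Draw `n` independent sub-seeds (31-bit) from the current stream.
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("gcmifc_usage_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("gcmifc_data_error", "error")))
}

# upper-triangle logical mask (no diagonal)
upper_mask <- function(n) upper.tri(matrix(0, n, n))
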