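#' @importFrom rlang %||% abort warn inform
#' @importFrom stats predict runif rnorm
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == as.integer(x) && x >= 1
}

# One log line to stderr; all readers/trainers funnel through here.
log_msg <- function(...) {
  inform(paste0(...))
}
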