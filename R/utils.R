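# Internal helpers shared across the pipeline stages.

# Derive a reproducible child seed from a master seed and an integer salt.
# Keeps every derived seed inside the 32-bit signed range.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %% 2147483647L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) && x >= min
}
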