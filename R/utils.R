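# Shared internal helpers.

# z multiplier used for every 95% interval in the package
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_maic <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a reproducible child seed from a master seed. Keeps results inside
# the 32-bit integer range R requires for set.seed().
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}
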