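# Shared internal helpers.

# Round-half-up to integer percent; matches how the source counts are reported
# (e.g. 436/800 = 54.5 -> 55).
round_half_up <- function(x) floor(x + 0.5)

# Derive the two sub-stream seeds (truth, counts) from one user seed, keeping
# both inside the 32-bit integer range.
truth_seed <- function(seed) as.integer(seed %% 2147400000L)
counts_seed <- function(seed) as.integer((seed + 104729L) %% 2147400000L)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
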