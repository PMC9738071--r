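## internal helpers -----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## derive k child seeds from one user seed; kept < 2^31 so they remain valid
## R integer seeds
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}
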