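#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

## Stop with a classed condition so callers can test errors by class rather
## than by message text.
cf_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "contextflux_error")))
}

## Deterministic derivation of per-stage seeds from one master seed.
## Kept strictly below 2^31 - 1 so the result is always a valid R integer.
derive_seed <- function(master_seed, counter) {
  master_seed <- as.double(master_seed)
  counter <- as.double(counter)
  as.integer((master_seed * 48271 + counter * 100003 + 12345) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
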