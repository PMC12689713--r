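`%||%` <- function(a, b) if (is.null(a)) b else a

## Seed scoping: all stochastic entry points take an optional `seed`;
## when given, the global RNG stream is set locally and restored on exit
## (Mersenne-Twister, R's default). `NULL` means "use the current stream".
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Deterministic sub-seed derivation so that one user seed can drive
## several independent generation steps without stream overlap.
.derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271L + as.integer(offset)) %% 2147483587L
}

.assert_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

.rmse <- function(x, y) sqrt(mean((x - y)^2))
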