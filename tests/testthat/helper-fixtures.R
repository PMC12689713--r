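## Shared fixtures; everything is generated in code, nothing on disk.

test_scheme <- breast_dki_scheme()

## a minimal scheme (N = 2): DKI's two decay parameters are exactly
## identified with a single b = 0
tiny_scheme <- acquisition_scheme(c(0, 1000, 2000))

## degenerate ranges that pin every sample to one fixed flat triple
fixed_triple_ranges <- function(s0 = 1000, d_scaled = 1.0, k = 0.8) {
  dki_ranges(s0 = c(s0, s0), d = c(d_scaled, d_scaled), k = c(k, k),
             w_s0 = c(0, 0), w_d = c(0, 0), w_k = c(0, 0))
}

## small phantom used across tests (fast to fit, >= 10^3 voxels/region)
small_phantom_spec <- function(dims = c(36, 36, 12), sigma = 32) {
  phantom_spec(dims = dims, sigma = sigma)
}

## independent forward model written out longhand (test-side oracle)
oracle_dki_signal <- function(b, s0, d, k) {
  s0 * exp(-b * d + (b^2 * d^2 * k) / 6)
}

## quick regressor for plumbing tests (not accuracy-critical)
quick_model <- function(dataset, target = "K", window = "synxqsl",
                        epochs = 10, seed = 42) {
  train_mlp(dataset, target, window,
            hyper = hyper_config(mid_layers = 2, units = 32, epochs = epochs),
            seed = seed)
}
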