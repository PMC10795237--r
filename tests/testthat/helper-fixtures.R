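# Small fixtures built in code.

## a deliberately tiny architecture for fast unit tests
tiny_config <- function(variant = "MSCAN", layers = 1L, dropout = 0) {
  model_config(d_model = 8L, heads = 2L, d_ff = 16L, layers = layers,
               dropout = dropout, scale_order = c(5L, 9L, 7L),
               d_embed = 8L, variant = variant)
}

## random scale bundle of d_model-wide matrices for sublayer tests
random_bundle_dm <- function(cfg, seed = 1L,
                             m = c(3L, 5L, 4L)) {
  withr::with_seed(seed, list(
    x = matrix(rnorm(m[1] * cfg$d_model), m[1], cfg$d_model),
    aux = list(c1 = matrix(rnorm(m[2] * cfg$d_model), m[2], cfg$d_model),
               c2 = matrix(rnorm(m[3] * cfg$d_model), m[3], cfg$d_model))))
}

## layer parameters drawn through the package initializer
tiny_layer_params <- function(cfg, seed = 1L) {
  build_variant(cfg$variant, cfg, seed = seed)$params$layers[[1L]]
}

## small strongly-signalled synthetic dataset
tiny_dataset <- function(n_pos = 10L, n_neg = 10L, seed = 1L,
                         signal = 1) {
  spec <- synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                         center_base = "A",
                         motif = random_pwm(8L, dominance = 0.97,
                                            seed = seed + 100L),
                         motif_offset = -4L, signal_strength = signal,
                         modification = "m6A", seed = seed)
  generate_dataset(spec)
}

## random valid 41-nt window
random_window <- function(seed = 1L) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "U"), 41L, replace = TRUE),
          collapse = ""))
}
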