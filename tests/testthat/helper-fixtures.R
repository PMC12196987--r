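# Shared fixtures: tiny configurations that keep unit tests fast while
# exercising every architectural element (d >= 2 down/up levels, multiple
# residual blocks and Transformer layers, several heads).

tiny_model_config <- function(...) {
  model_config(n = 4L, l0 = 16L, l = 16L, d = 2L, r = 2L, heads = 2L,
               L = 2L, base_channels = 2L, mlp_expansion = 2L,
               dropout = 0, ...)
}

reduced_model_config <- function(...) {
  model_config(n = 15L, base_channels = 8L, r = 2L, L = 1L, ...)
}

quick_record <- function(duration_s = 60, seed = 3, ...) {
  generate_record(sim_config(duration_s = duration_s, seed = seed, ...))
}

# deterministic random sequence pairs for metric tests
random_pairs <- function(m, n = 60L, seed = 1) {
  set.seed(seed)
  list(gt = matrix(120 + rnorm(m * n, sd = 8), m, n),
       pred = matrix(120 + rnorm(m * n, sd = 8), m, n))
}
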