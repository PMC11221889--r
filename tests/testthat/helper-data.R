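# Small synthetic datasets and models shared across test files.

small_dataset <- function(n_complexes = 2L, mutations_per_complex = 4L,
                          noise_sd = 0, seed = 11L,
                          ag_len = c(20L, 30L), ab_len = c(25L, 35L)) {
  generate_dataset(synthetic_config(
    n_complexes = n_complexes,
    mutations_per_complex = mutations_per_complex,
    antigen_length_range = ag_len, antibody_length_range = ab_len,
    interface_width = 6L, noise_sd = noise_sd, seed = seed))
}

small_model <- function(hidden_size = 4L, n_heads = 2L, dropout = 0,
                        use_attention = TRUE, seed = 5L) {
  init_model(model_config(hidden_size = hidden_size, n_heads = n_heads,
                          fc_sizes = c(16L, 8L, 4L),
                          dropout_rate = dropout,
                          use_attention = use_attention, seed = seed))
}

random_features <- function(n_ab, n_ag, seed = 1L) {
  withr::with_seed(seed, list(
    ab_wt = matrix(rnorm(n_ab * 40), n_ab, 40),
    ag_wt = matrix(rnorm(n_ag * 40), n_ag, 40),
    ab_mt = matrix(rnorm(n_ab * 40), n_ab, 40),
    ag_mt = matrix(rnorm(n_ag * 40), n_ag, 40)))
}

# memoised heavy benchmark results shared by several acceptance checks
.benchmark_cache <- new.env(parent = emptyenv())

cached_benchmark <- function(key, fun) {
  if (is.null(.benchmark_cache[[key]]))
    .benchmark_cache[[key]] <- fun()
  .benchmark_cache[[key]]
}
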