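# Shared fixtures: small synthetic datasets and reduced-width model configs
# used across test files.  Everything is generated in code at test time.

# Quarter-width architecture: identical level structure and shapes in
# length, reduced channel widths; fast enough for training-based tests.
small_config <- function(...) {
  model_config(channels = c(16L, 32L, 48L, 64L), se_ratio = 8, ...)
}

# Very small config for numerical gradient checks (double precision).
tiny_config <- function() {
  model_config(input_len = 250L, channels = c(4L, 6L, 8L, 10L),
               se_ratio = 2, ap_windows = c(5L, 25L), sa_reduce = 2,
               sa_min_mid = 2, sa_kernel = 4, ca_ratio = 2,
               head_dense = c(8L, 6L, 4L))
}

make_easy_dataset <- function(n_per_class = 10, seed = 42, n_beats = 10L) {
  tmpl <- synth_preset("easy", n_beats = n_beats)
  recs <- synth_dataset(n_per_class,
                        list(normal = tmpl, abnormal = tmpl), seed = seed)
  build_dataset(recs)
}

rand_waves <- function(n, len = 2000L, seed = 1) {
  with_seed <- cardiofuse:::with_seed
  with_seed(seed, matrix(stats::rnorm(len * n), len, n))
}
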