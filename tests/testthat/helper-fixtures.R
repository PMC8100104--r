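# Shared fixtures: tiny synthetic datasets and models, kept small enough
# that every unit test runs in well under a second.

tiny_spec <- function(seed = 7L, motif_lengths = c(8L, 6L, 5L)) {
  build_family_spec(3L, 2L, 2L, motif_lengths = motif_lengths, seed = seed)
}

tiny_dataset <- function(n_per_class = 5L, length = 120L, mutation_rate = 0,
                         seed = 7L) {
  simulate_sequences(tiny_spec(seed), n_per_class = n_per_class,
                     length = length, mutation_rate = mutation_rate,
                     seed = seed)
}

tiny_config <- function(...) {
  model_config(kernel_sizes = c(4L, 6L), filters_per_kernel = 6L,
               embed_dim = 8L, classifier_hidden = 6L, max_len = 120L, ...)
}

tiny_model <- function(dataset = tiny_dataset(), seed = 1L, ...) {
  build_model(tiny_config(...), dataset$hierarchy, seed = seed)
}

# brute-force convolution + ReLU + one-max pooling for one filter,
# independent of the package's GEMM-based implementation
brute_conv_max <- function(idx_row, W_filter, bias) {
  # W_filter: k x 20 matrix
  k <- nrow(W_filter)
  L <- length(idx_row)
  best <- -Inf
  for (p in 1:(L - k + 1)) {
    resp <- bias
    for (j in 1:k) {
      a <- idx_row[p + j - 1]
      if (a > 0) resp <- resp + W_filter[j, a]
    }
    best <- max(best, max(resp, 0))
  }
  best
}

# reshape a packed conv weight matrix (20 x (k*F)) into per-filter k x 20
unpack_filter <- function(W, k, n_filters, f) {
  t(W[, (seq_len(k) - 1L) * n_filters + f, drop = FALSE])
}
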