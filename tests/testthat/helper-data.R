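# Shared fixture builders. Everything is generated in code, seeded, and
# small enough to keep the suite fast.

tiny_counts <- function(n_cells = 6, n_genes = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda = 4), n_cells, n_genes,
              dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                              sprintf("g%02d", seq_len(n_genes))))
  expression_dataset(m)
}

# Small five-type RNA simulation with clearly separable types.
quick_sim <- function(n_cells = 400, n_genes = 100, marker_effect = 3,
                      seed = 11, ...) {
  simulate_cells(generator_config(n_cells = n_cells, n_genes = n_genes,
                                  marker_effect = marker_effect,
                                  seed = seed, ...))
}

# Two well-separated Gaussian blobs in feature space, for classifier
# sanity checks.
blob_matrix <- function(n_per = 30, d = 5, shift = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = shift), n_per, d))
  rownames(x) <- sprintf("b%03d", seq_len(2 * n_per))
  colnames(x) <- paste0("f", seq_len(d))
  labels <- tibble::tibble(cell_id = rownames(x),
                           cell_type = rep(c("A", "B"), each = n_per))
  list(x = x, labels = labels)
}

uniform_probs <- function(n, k, ids = sprintf("u%03d", seq_len(n))) {
  matrix(1 / k, n, k, dimnames = list(ids, paste0("t", seq_len(k))))
}
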