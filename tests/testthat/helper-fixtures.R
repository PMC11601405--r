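# Fixture builders and independent oracles shared across the test files.

random_binary_matrix <- function(n, m, density, seed) {
  withr::with_seed(seed, matrix(stats::runif(n * m) < density, n, m))
}

# logical matrix from 0/1 row vectors
bin_from_rows <- function(...) {
  m <- do.call(rbind, list(...))
  mode(m) <- "logical"
  m
}

# upper-tail hypergeometric probability by direct summation of the
# probability mass (binomial-coefficient ratio), independent of phyper
hyper_tail_oracle <- function(N, K, n, k) {
  if (k <= max(0, n - (N - K))) return(1)  # overlap can never fall below this
  hi <- min(K, n)
  if (k > hi) return(0)
  js <- k:hi
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# canonical signature of a partition, invariant under label renaming
partition_key <- function(labels) {
  groups <- split(seq_along(labels), labels)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = "|")
}

# small synthetic dataset shared by workflow tests
small_sim_spec <- function(n_noise_terms = 10) {
  list(n_traits = 60, n_genes = 150,
       blocks = list(list(rows = 5, cols = 12),
                     list(rows = 5, cols = 12),
                     list(rows = 5, cols = 12)),
       signal_p_max = 1e-12, background_sig_rate = 0,
       annotation_noise_terms = n_noise_terms)
}
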