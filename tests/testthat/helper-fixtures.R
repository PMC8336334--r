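# shared fixtures and small utilities for the test suite

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small named gene x sample matrix with reproducible values
rand_expr <- function(n_genes, n_samples, seed = 1, min = 0, max = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_samples, min, max), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# exact low-rank non-negative matrix, for NMF reconstruction checks
rank_k_matrix <- function(n, m, k, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  V <- W %*% H
  dimnames(V) <- list(sprintf("g%03d", seq_len(n)), sprintf("s%03d", seq_len(m)))
  V
}

# two well-separated sample blocks: block b gets a mean shift on its own genes
block_matrix <- function(n_genes = 40, per_block = 10, shift = 4,
                         noise = 0.05, seed = 1) {
  set.seed(seed)
  n_samples <- 2 * per_block
  m <- matrix(stats::rnorm(n_genes * n_samples, 1, noise), n_genes, n_samples)
  m[1:(n_genes / 2), 1:per_block] <- m[1:(n_genes / 2), 1:per_block] + shift
  m[(n_genes / 2 + 1):n_genes, (per_block + 1):n_samples] <-
    m[(n_genes / 2 + 1):n_genes, (per_block + 1):n_samples] + shift
  m <- m - min(m)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

# small, fast simulator preset for pipeline-level unit tests
small_sim <- function(seed = 1) {
  simulate_tme(sim_params(n_genes = 400L, n_samples = 100L,
                          n_immune_genes = 30L, n_stromal_genes = 20L,
                          n_noise_factors = 2L, noise_module_size = 25L,
                          seed = seed))
}

tmp_path <- function(ext) tempfile(fileext = ext)
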