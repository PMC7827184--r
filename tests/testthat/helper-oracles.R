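# Independent oracles and small fixture builders shared across tests.

# Naive double-loop evaluation of the PsePSSM definition: column means then,
# for each lag g, mean squared lagged column differences. Deliberately
# written element-by-element, independent of the package's vectorized path.
naive_psepssm <- function(mat, lag_max) {
  L <- nrow(mat)
  out <- numeric(0)
  for (j in 1:20) out <- c(out, sum(mat[, j]) / L)
  for (g in seq_len(lag_max)) {
    for (j in 1:20) {
      acc <- 0
      for (i in seq_len(L - g)) acc <- acc + (mat[i, j] - mat[i + g, j])^2
      out <- c(out, acc / (L - g))
    }
  }
  out
}

# Random matrix with entries in (0,1), mimicking a normalized PSSM.
random_normalized_matrix <- function(L) {
  m <- matrix(stats::runif(L * 20), L, 20)
  colnames(m) <- pssm_alphabet()
  m
}

random_sequence <- function(L) {
  paste(sample(pssm_alphabet(), L, replace = TRUE), collapse = "")
}

# A tiny ready-made study: sequences, PSSMs, dataset, features.
tiny_truth <- function(seed = 42L, n_proteins = 3L, n_mutations = 8L) {
  synth_dataset(synth_config(n_proteins = n_proteins,
                             length_range = c(40L, 60L),
                             n_mutations = n_mutations,
                             noise_sd = 0.3, seed = seed))
}
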