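# Small fixture builders shared across the suite; everything is generated
# in code so tests are self-contained.

tiny_dataset <- function(n0 = 30, n1 = 10, p = 8, k = 2, effect = 2,
                         seed = 42) {
  generate_dataset(generator_spec(n0, n1, n_features = p, n_informative = k,
                                  effect_size = effect, seed = seed))
}

# two well-separated point clouds in 2-D, deterministic
blob_pair <- function(n = 20, gap = 10) {
  x <- rbind(cbind(rnorm(n), rnorm(n)),
             cbind(rnorm(n) + gap, rnorm(n)))
  list(x = x, y = rep(c(0L, 1L), each = n))
}

# independent Floyd-Warshall all-pairs shortest paths (O(n^3) oracle)
floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  D[D == 0 & row(D) != col(D)] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}
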