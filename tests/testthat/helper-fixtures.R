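# Small in-code fixtures shared across tests.

# Two well-separated Gaussian clusters in d dimensions.
make_clusters <- function(n_per = 10, d = 2, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d) + sep, n_per, d))
  })
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- sprintf("f%04d", seq_len(d))
  out$label <- rep(c(-1, 1), each = n_per)
  out
}

# A fast low-replicate simulator configuration.
tiny_config <- function(replicates = 3, seed = 42, ...) {
  sim_config(replicates = replicates, seed = seed, ...)
}

# Brute-force O(n^2) AUC oracle: pairwise positive/negative comparisons.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force argmax-over-labels voting oracle.
vote_bruteforce <- function(pred_mat, weights) {
  apply(pred_mat, 1, function(v) {
    w_pos <- sum(weights[v == 1])
    w_neg <- sum(weights[v == -1])
    if (w_pos >= w_neg) 1 else -1
  })
}
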