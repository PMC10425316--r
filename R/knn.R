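# K-nearest-neighbor vote used throughout the pipeline (base wrapper-fitness
# classifier, agent evaluation, and final prediction over prototypes).
#
# Tie rules are deterministic by construction:
#  - distance ties are broken by lower reference index (stable order),
#  - an even vote split is broken by the nearest neighbor's label.
knn_predict <- function(ref, ref_labels, query, k) {
  ref <- as.matrix(ref)
  query <- as.matrix(query)
  n_ref <- nrow(ref)
  k <- min(k, n_ref)
  r2 <- rowSums(ref^2)
  q2 <- rowSums(query^2)
  d2 <- outer(q2, r2, "+") - 2 * (query %*% t(ref))
  out <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- order(d2[i, ], seq_len(n_ref))
    nn <- ord[seq_len(k)]
    votes <- sum(ref_labels[nn] == 1L)
    out[i] <- if (2L * votes > k) 1L
      else if (2L * votes < k) 0L
      else ref_labels[nn[1L]]
  }
  out
}
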