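# Independent brute-force oracles and small data builders used across tests.
# The oracles deliberately avoid the package's vectorized code paths: plain
# double loops, explicit distance sorts, same declared tie rules
# (distance ties -> lower reference index; even vote split -> nearest label).

brute_knn <- function(ref, ref_labels, query, k) {
  ref <- as.matrix(ref)
  query <- as.matrix(query)
  out <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(ref))
    for (j in seq_len(nrow(ref))) {
      d[j] <- sqrt(sum((query[i, ] - ref[j, ])^2))
    }
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(min(k, length(d)))]
    votes <- sum(ref_labels[nn] == 1L)
    kk <- length(nn)
    out[i] <- if (2L * votes > kk) 1L
      else if (2L * votes < kk) 0L
      else ref_labels[nn[1L]]
  }
  out
}

# Scalar re-derivation of an agent's fitness: hand-rolled class-major layout
# decode plus the brute-force KNN vote, averaged over training cases.
brute_eval_agent <- function(position, train_w, train_labels, A, n_c, k) {
  v <- 2L * n_c
  protos <- matrix(0, nrow = v, ncol = A)
  labels <- integer(v)
  idx <- 1L
  row <- 1L
  for (cl in c(1L, 0L)) {
    for (j in seq_len(n_c)) {
      for (f in seq_len(A)) {
        protos[row, f] <- position[idx]
        idx <- idx + 1L
      }
      labels[row] <- cl
      row <- row + 1L
    }
  }
  pred <- brute_knn(protos, labels, train_w, min(k, v))
  mean(pred == train_labels)
}

# Two well-separated Gaussian classes as a biomarker_dataset.
make_separable <- function(n_per = 20L, p = 3L, gap = 4, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), ncol = p),
             matrix(rnorm(n_per * p, mean = gap), ncol = p))
  biomarker_dataset(x, rep(c(0L, 1L), each = n_per))
}

write_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
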