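#' Wrapper fitness of a feature mask
#'
#' Trains the internal base classifier — the naive-Bayes-weighted KNN with
#' `k = 3` — on the masked training features and returns its validation
#' accuracy minus a sparsity penalty proportional to the selected fraction:
#' `accuracy - penalty * n_selected / n_total`. A mask selecting no feature
#' scores 0.
#'
#' @param mask logical vector, one entry per feature (`TRUE` = keep).
#' @param train,val [biomarker_dataset]s sharing the feature set.
#' @param penalty sparsity penalty weight, `>= 0`. Default 0.01.
#' @param k neighbors of the base classifier. Default 3.
#' @return Fitness in `(-penalty, 1]`; 0 for the empty mask.
#' @export
mask_fitness <- function(mask, train, val, penalty = 0.01, k = 3L) {
  mask <- as.logical(mask)
  if (length(mask) != length(train$feature_names)) {
    stopf("mask length %d != %d features", length(mask),
          length(train$feature_names))
  }
  if (!any(mask)) return(0)
  pred <- weighted_knn(train[, mask], val$values[, mask, drop = FALSE], k = k)
  mean(pred == val$labels) - penalty * sum(mask) / length(mask)
}

#' Binary grey wolf feature selection
#'
#' Wrapper feature selection with a binary grey wolf optimizer: a pack of
#' wolves holds continuous positions in `[0, 1]` per feature; each position
#' is binarized through a sigmoid transfer function with Bernoulli
#' thresholding into a candidate feature mask, scored by [mask_fitness()].
#' The three fittest masks (alpha, beta, delta) steer the continuous
#' encircling updates with the control coefficient `a` decreasing linearly
#' from 2 to 0 over the iterations. The best mask ever evaluated is retained
#' (elitism) and returned, so best fitness is non-decreasing in iterations.
#'
#' @param train,val [biomarker_dataset]s sharing the feature set.
#' @param population_size wolves in the pack, at least 4. Default 20.
#' @param max_iter iterations. Default 100.
#' @param penalty sparsity penalty passed to [mask_fitness()]. Default 0.01.
#' @param k base-classifier neighbors. Default 3.
#' @param seed integer seed; the run is deterministic given it.
#' @return Logical feature mask with attributes `fitness` (best fitness) and
#'   `history` (best-so-far fitness per iteration, length `max_iter + 1`).
#' @export
run_bgwo <- function(train, val, population_size = 20L, max_iter = 100L,
                     penalty = 0.01, k = 3L, seed = 1L) {
  if (!is_count(population_size, 4L)) {
    stopf("population_size must be >= 4 (three leaders + pack)")
  }
  if (!is_count(max_iter)) stopf("max_iter must be a positive integer")
  p <- length(train$feature_names)
  if (p == 1L) {
    mask <- TRUE
    attr(mask, "fitness") <- mask_fitness(TRUE, train, val, penalty, k)
    attr(mask, "history") <- rep(attr(mask, "fitness"), max_iter + 1L)
    return(mask)
  }
  set.seed(seed)
  n <- population_size
  pos <- matrix(stats::runif(n * p), nrow = n)

  sample_mask <- function(x) stats::runif(p) < sigmoid(10 * (x - 0.5))
  masks <- t(apply(pos, 1L, sample_mask))
  fit <- vapply(seq_len(n), function(i) {
    mask_fitness(masks[i, ], train, val, penalty, k)
  }, numeric(1L))

  best_i <- which.max(fit)
  best_mask <- masks[best_i, ]
  best_fit <- fit[best_i]
  history <- numeric(max_iter + 1L)
  history[1L] <- best_fit

  for (iter in seq_len(max_iter)) {
    a <- 2 - 2 * iter / max_iter
    lead <- order(-fit, seq_len(n))[1:3]
    lead_pos <- pos[lead, , drop = FALSE]
    for (i in seq_len(n)) {
      x_new <- numeric(p)
      for (l in 1:3) {
        aa <- 2 * a * stats::runif(p) - a
        cc <- 2 * stats::runif(p)
        d <- abs(cc * lead_pos[l, ] - pos[i, ])
        x_new <- x_new + (lead_pos[l, ] - aa * d)
      }
      pos[i, ] <- clip(x_new / 3, 0, 1)
      masks[i, ] <- sample_mask(pos[i, ])
      fit[i] <- mask_fitness(masks[i, ], train, val, penalty, k)
      if (fit[i] > best_fit) {
        best_fit <- fit[i]
        best_mask <- masks[i, ]
      }
    }
    history[iter + 1L] <- best_fit
  }
  names(best_mask) <- train$feature_names
  attr(best_mask, "fitness") <- best_fit
  attr(best_mask, "history") <- history
  best_mask
}
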