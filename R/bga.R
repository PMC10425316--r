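#' Fitness of a training-row mask
#'
#' Validation accuracy of the base classifier (naive-Bayes-weighted KNN,
#' `k = 3`) trained on the kept rows only. Masks keeping fewer than two rows
#' of either class score 0: the weighting stage needs at least two samples
#' per class to estimate a variance, so such masks are invalid by
#' construction.
#'
#' @param mask logical vector, one entry per training row (`TRUE` = keep).
#' @param train,val [biomarker_dataset]s sharing the feature set.
#' @param k base-classifier neighbors. Default 3.
#' @return Validation accuracy in `[0, 1]`; 0 for invalid masks.
#' @export
rowmask_fitness <- function(mask, train, val, k = 3L) {
  mask <- as.logical(mask)
  if (length(mask) != length(train$labels)) {
    stopf("mask length %d != %d training rows", length(mask),
          length(train$labels))
  }
  kept <- train$labels[mask]
  if (sum(kept == 0L) < 2L || sum(kept == 1L) < 2L) return(0)
  pred <- weighted_knn(train[mask, ], val$values, k = k)
  mean(pred == val$labels)
}

#' Binary genetic algorithm outlier rejection
#'
#' A generational genetic algorithm over keep/drop bits, one per training
#' row, scored by [rowmask_fitness()]: binary tournament selection (the
#' fitter competitor wins with probability `p_selection`), single-point
#' crossover applied to each pair with probability `p_crossover`, and
#' independent per-bit flip mutation with probability `p_mutation`. In
#' `"random"` mode (the default) all three probabilities are redrawn
#' uniformly from `[0, 1]` at every generation; `"fixed"` mode holds them at
#' the supplied values and is the reproducible benchmarking configuration.
#' The best individual survives each generation unchanged and the best mask
#' ever evaluated is returned, so best fitness is non-decreasing.
#'
#' The population is initialized with a bias toward keeping rows (keep
#' probability 0.8, plus the all-keep individual): outlier rejection starts
#' from the presumption that most training data is valid and searches for
#' the few rows whose removal raises validation accuracy.
#'
#' @param train,val [biomarker_dataset]s sharing the feature set.
#' @param population_size individuals per generation, at least 2. Default 30.
#' @param max_iter generations. Default 100.
#' @param mode `"random"` (probabilities redrawn each generation, the
#'   default) or `"fixed"`.
#' @param p_crossover,p_mutation,p_selection probabilities used in `"fixed"`
#'   mode. Defaults 0.9, 0.02, 0.9.
#' @param k base-classifier neighbors. Default 3.
#' @param seed integer seed; the run is deterministic given it.
#' @return Logical keep-mask named by sample id, with attributes `fitness`
#'   and `history` (best-so-far fitness per generation).
#' @export
run_bga <- function(train, val, population_size = 30L, max_iter = 100L,
                    mode = c("random", "fixed"), p_crossover = 0.9,
                    p_mutation = 0.02, p_selection = 0.9, k = 3L, seed = 1L) {
  mode <- match.arg(mode)
  n_rows <- length(train$labels)
  if (n_rows == 0L) stopf("empty training set")
  if (!is_count(population_size, 2L)) stopf("population_size must be >= 2")
  if (!is_count(max_iter)) stopf("max_iter must be a positive integer")
  set.seed(seed)
  n <- population_size

  pop <- matrix(stats::runif(n * n_rows) < 0.8, nrow = n)
  pop[1L, ] <- TRUE
  fit <- vapply(seq_len(n), function(i) {
    rowmask_fitness(pop[i, ], train, val, k)
  }, numeric(1L))

  best_i <- which.max(fit)
  best_mask <- pop[best_i, ]
  best_fit <- fit[best_i]
  history <- numeric(max_iter + 1L)
  history[1L] <- best_fit

  tournament <- function(p_sel) {
    pair <- sample.int(n, 2L)
    fitter <- pair[order(-fit[pair], pair)[1L]]
    other <- setdiff(pair, fitter)[1L]
    if (stats::runif(1L) < p_sel) fitter else other
  }

  for (gen in seq_len(max_iter)) {
    if (mode == "random") {
      p_crossover <- stats::runif(1L)
      p_mutation <- stats::runif(1L)
      p_selection <- stats::runif(1L)
    }
    elite <- pop[order(-fit, seq_len(n))[1L], ]
    offspring <- matrix(FALSE, nrow = n, ncol = n_rows)
    offspring[1L, ] <- elite
    i <- 2L
    while (i <= n) {
      a <- pop[tournament(p_selection), ]
      b <- pop[tournament(p_selection), ]
      if (stats::runif(1L) < p_crossover && n_rows > 1L) {
        cut <- sample.int(n_rows - 1L, 1L)
        tmp <- a
        a <- c(a[seq_len(cut)], b[(cut + 1L):n_rows])
        b <- c(b[seq_len(cut)], tmp[(cut + 1L):n_rows])
      }
      for (child in list(a, b)) {
        if (i > n) break
        flip <- stats::runif(n_rows) < p_mutation
        offspring[i, ] <- xor(child, flip)
        i <- i + 1L
      }
    }
    pop <- offspring
    fit <- vapply(seq_len(n), function(j) {
      rowmask_fitness(pop[j, ], train, val, k)
    }, numeric(1L))
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit) {
      best_fit <- fit[gen_best]
      best_mask <- pop[gen_best, ]
    }
    history[gen + 1L] <- best_fit
  }
  # guarantee the per-class minimum on output even if search never improved
  if (sum(train$labels[best_mask] == 0L) < 2L ||
      sum(train$labels[best_mask] == 1L) < 2L) {
    best_mask <- rep(TRUE, n_rows)
    best_fit <- rowmask_fitness(best_mask, train, val, k)
  }
  names(best_mask) <- train$sample_ids
  attr(best_mask, "fitness") <- best_fit
  attr(best_mask, "history") <- history
  best_mask
}
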