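#' Fit the naive-Bayes feature-to-weight mapping
#'
#' Estimates, per class and feature, Gaussian class-conditional parameters on
#' the training split, after z-scoring each feature with training-split
#' statistics (blood-protein levels span orders of magnitude; without
#' standardization nearest-neighbor distances degenerate). The fitted mapping
#' carries everything needed to project new samples into weight space with
#' [to_weight_space()].
#'
#' @param train a [biomarker_dataset] with at least two samples per class.
#' @param sigma_floor lower bound applied to every fitted standard deviation
#'   so constant features cannot produce degenerate densities. Default 1e-6.
#' @return An object of class `weight_mapping`: z-scoring `center`/`scale`,
#'   matrices `mu` and `sigma` (2 x n_features, rows = classes 0 and 1),
#'   `priors` (length 2, summing to 1), `feature_names`, `classes`.
#' @export
fit_weighting <- function(train, sigma_floor = 1e-6) {
  stopifnot(inherits(train, "biomarker_dataset"))
  counts <- c(sum(train$labels == 0L), sum(train$labels == 1L))
  if (any(counts < 2L)) {
    stopf("each class needs >= 2 training samples (have %d and %d)",
          counts[1L], counts[2L])
  }
  x <- train$values
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale < sigma_floor] <- 1
  z <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  mu <- rbind(colMeans(z[train$labels == 0L, , drop = FALSE]),
              colMeans(z[train$labels == 1L, , drop = FALSE]))
  sigma <- rbind(apply(z[train$labels == 0L, , drop = FALSE], 2L, stats::sd),
                 apply(z[train$labels == 1L, , drop = FALSE], 2L, stats::sd))
  sigma[sigma < sigma_floor] <- sigma_floor
  rownames(mu) <- rownames(sigma) <- c("class0", "class1")
  structure(
    list(center = center, scale = scale, mu = mu, sigma = sigma,
         priors = counts / sum(counts),
         feature_names = train$feature_names, classes = train$classes),
    class = "weight_mapping"
  )
}

#' Project samples from feature space into naive-Bayes weight space
#'
#' Each feature value is replaced by its normalized class-conditional
#' evidence: for feature `f` and class `c`, the coordinate is
#' `p_c(x_f) / (p_0(x_f) + p_1(x_f))`, where `p_c` is the fitted Gaussian
#' density. The two coordinates of a feature always sum to one and each lies
#' in `[0, 1]`, so the weight space is bounded and distance-friendly.
#' Computation goes through log densities, so extreme tail values stay
#' well-defined.
#'
#' @param w a [fit_weighting()] mapping.
#' @param x a numeric vector (one sample), a matrix (samples x features), or
#'   a [biomarker_dataset].
#' @return A matrix with `2 * n_features` columns; columns are ordered
#'   feature-major, the class-0 then the class-1 coordinate of feature 1,
#'   then feature 2, and so on.
#' @export
to_weight_space <- function(w, x) {
  stopifnot(inherits(w, "weight_mapping"))
  if (inherits(x, "biomarker_dataset")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  p <- length(w$feature_names)
  if (ncol(x) != p) {
    stopf("sample has %d features; mapping expects %d", ncol(x), p)
  }
  z <- sweep(sweep(x, 2L, w$center), 2L, w$scale, "/")
  out <- matrix(0, nrow = nrow(x), ncol = 2L * p)
  for (f in seq_len(p)) {
    l0 <- stats::dnorm(z[, f], w$mu[1L, f], w$sigma[1L, f], log = TRUE)
    l1 <- stats::dnorm(z[, f], w$mu[2L, f], w$sigma[2L, f], log = TRUE)
    w1 <- 1 / (1 + exp(l0 - l1))
    out[, 2L * f - 1L] <- 1 - w1
    out[, 2L * f] <- w1
  }
  colnames(out) <- as.vector(rbind(paste0(w$feature_names, ".c0"),
                                   paste0(w$feature_names, ".c1")))
  out
}

#' Naive-Bayes class prediction (test oracle)
#'
#' A plain Gaussian naive-Bayes posterior classifier over the fitted mapping.
#' It is not part of the diagnostic pipeline; it exists as an independent
#' reference against which the weight-space construction can be checked.
#'
#' @param w a [fit_weighting()] mapping.
#' @param x samples as in [to_weight_space()].
#' @return Integer 0/1 predictions.
#' @export
predict_nb <- function(w, x) {
  stopifnot(inherits(w, "weight_mapping"))
  if (inherits(x, "biomarker_dataset")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  z <- sweep(sweep(x, 2L, w$center), 2L, w$scale, "/")
  ll0 <- log(w$priors[1L])
  ll1 <- log(w$priors[2L])
  for (f in seq_len(ncol(z))) {
    ll0 <- ll0 + stats::dnorm(z[, f], w$mu[1L, f], w$sigma[1L, f], log = TRUE)
    ll1 <- ll1 + stats::dnorm(z[, f], w$mu[2L, f], w$sigma[2L, f], log = TRUE)
  }
  as.integer(ll1 > ll0)
}

# Weighted KNN: the KN3B-style base classifier used by the wrapper fitness
# functions — fit the NB weighting on train, map both splits to weight space,
# and classify by K-nearest-neighbor vote over the full weighted training set.
weighted_knn <- function(train, test_values, k = 3L) {
  w <- fit_weighting(train)
  wt <- to_weight_space(w, train)
  wq <- to_weight_space(w, test_values)
  knn_predict(wt, train$labels, wq, k)
}
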