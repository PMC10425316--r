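test_that("the fitted classifier separates clean synthetic panels on holdout", {
  gen <- generate_biomarkers(synthetic_spec(outlier_rate = 0, seed = 7L))
  parts <- stratified_split(gen$dataset, seed = 3L)
  m <- eknn(parts$train, seed = 5L)
  expect_s3_class(m, "eknn")
  expect_lt(nrow(m$prototypes), length(parts$train$labels))  # v < Q
  acc <- mean(predict(m, parts$test) == parts$test$labels)
  expect_gte(acc, 0.9)
})

test_that("an oversized prototype budget is rejected", {
  d <- make_separable(n_per = 4L, p = 2L, gap = 5, seed = 2L)
  expect_error(eknn(d, n_c = 4L), "must be < Q")
})

test_that("models survive JSON serialization with identical predictions", {
  d <- make_separable(n_per = 15L, p = 3L, gap = 4, seed = 3L)
  m <- eknn(d, n_c = 2L, max_iter = 20L, seed = 9L)
  path <- tempfile(fileext = ".json")
  write_eknn(m, path)
  m2 <- read_eknn(path)
  q <- make_separable(n_per = 10L, p = 3L, gap = 4, seed = 4L)
  expect_identical(predict(m, q$values), predict(m2, q$values))
})

test_that("prediction follows the K-nearest prototype vote with stable tie rules", {
  # hand-built model in raw (z-scored-identity) space: one prototype per class
  w <- structure(list(center = c(0, 0), scale = c(1, 1),
                      mu = matrix(0, 2, 2), sigma = matrix(1, 2, 2),
                      priors = c(0.5, 0.5), feature_names = c("a", "b"),
                      classes = c("TD", "ASD")), class = "weight_mapping")
  m <- structure(list(weighting = w,
                      prototypes = rbind(c(1, 1), c(-1, -1)),
                      proto_labels = c(1L, 0L), k = 1L, weight = FALSE,
                      classes = c("TD", "ASD"), n_train = 4L, coa = NULL,
                      seed = 1L), class = "eknn")
  expect_equal(predict(m, c(1, 1)), 1L)        # at the class-1 prototype
  expect_equal(predict(m, c(-1, -1)), 0L)
  expect_equal(predict(m, c(0, 0)), 1L)        # equidistant -> index-first prototype
  expect_equal(predict(m, c(1, 1), type = "class"), "ASD")
  expect_error(predict(m, c(1, 2, 3)), "expects 2")
})

test_that("k = 1 prediction matches the exhaustive nearest-prototype oracle", {
  d <- make_separable(n_per = 20L, p = 3L, gap = 3, seed = 6L)
  m <- eknn(d, k = 1L, n_c = 3L, max_iter = 30L, seed = 7L)
  set.seed(8)
  queries <- matrix(rnorm(500 * 3, mean = 1.5, sd = 2), ncol = 3)
  got <- predict(m, queries)
  wq <- to_weight_space(m$weighting, queries)
  want <- brute_knn(m$prototypes, m$proto_labels, wq, k = 1L)
  expect_identical(got, want)
})

test_that("without reduction the classifier is exactly the weighted KNN", {
  d <- make_separable(n_per = 20L, p = 3L, gap = 3, seed = 9L)
  q <- make_separable(n_per = 15L, p = 3L, gap = 3, seed = 10L)
  m <- eknn(d, reduce = FALSE, seed = 1L)
  w <- fit_weighting(d)
  want <- brute_knn(to_weight_space(w, d), d$labels,
                    to_weight_space(w, q), k = 3L)
  expect_identical(predict(m, q$values), want)
})

test_that("without weighting the classifier reduces to plain KNN on z-scores", {
  d <- make_separable(n_per = 20L, p = 3L, gap = 3, seed = 11L)
  q <- make_separable(n_per = 15L, p = 3L, gap = 3, seed = 12L)
  m <- eknn(d, reduce = FALSE, weight = FALSE, seed = 1L)
  center <- colMeans(d$values)
  scale <- apply(d$values, 2, sd)
  z <- sweep(sweep(d$values, 2, center), 2, scale, "/")
  zq <- sweep(sweep(q$values, 2, center), 2, scale, "/")
  want <- brute_knn(z, d$labels, zq, k = 3L)
  expect_identical(predict(m, q$values), want)
})

test_that("the formula interface mirrors the matrix interface", {
  d <- make_separable(n_per = 15L, p = 2L, gap = 4, seed = 13L)
  df <- data.frame(d$values, label = d$classes[d$labels + 1L])
  m1 <- eknn(label ~ ., data = df, n_c = 2L, max_iter = 20L, seed = 5L)
  m2 <- eknn(d, n_c = 2L, max_iter = 20L, seed = 5L)
  q <- make_separable(n_per = 5L, p = 2L, gap = 4, seed = 14L)
  expect_identical(predict(m1, q$values), predict(m2, q$values))
})

test_that("neighbor-count selection minimizes validation error with a smallest-k tie rule", {
  d <- make_separable(n_per = 30L, p = 2L, gap = 1.2, seed = 15L)
  parts <- stratified_split(d, 0.5, 0.5, 0, seed = 9L)
  k_range <- 1:5
  # independent oracle: per-k validation error via the brute-force classifier
  errs <- vapply(k_range, function(kk) {
    w <- fit_weighting(parts$train)
    pred <- brute_knn(to_weight_space(w, parts$train), parts$train$labels,
                      to_weight_space(w, parts$validation), k = kk)
    mean(pred != parts$validation$labels)
  }, numeric(1))
  want <- k_range[order(errs, k_range)[1L]]
  got <- select_k(parts$train, parts$validation, k_range)
  expect_equal(as.integer(got), want)
  expect_equal(unname(attr(got, "errors")), errs)

  expect_equal(as.integer(select_k(parts$train, parts$validation, 4L)), 4L)
  expect_error(select_k(parts$train, parts$validation, integer(0)), "empty")
})
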