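constant_member <- function(value, name = "CONST") {
  structure(list(name = name,
                 fit = function(train, seed = 1L) value,
                 predict = function(model, values) rep(model, nrow(values))),
            class = "classifier_contract")
}

failing_member <- function() {
  structure(list(name = "BROKEN",
                 fit = function(train, seed = 1L) stop("boom"),
                 predict = function(model, values) stop("unreachable")),
            class = "classifier_contract")
}

test_that("best-method selection is argmax with first-member tie break", {
  expect_equal(select_best(c(SVM = 0.75, DLA = 0.82, EKNN = 0.91)), "EKNN")
  expect_equal(select_best(c(EKNN = 0.5)), "EKNN")
  expect_equal(select_best(c(SVM = 0.8, EKNN = 0.8)), "SVM")
  expect_error(select_best(numeric(0)), "empty")

  # property: always attains the maximum (checked against a sort-based oracle)
  set.seed(17)
  for (i in 1:200) {
    acc <- runif(sample(1:6, 1))
    names(acc) <- paste0("m", seq_along(acc))
    best <- select_best(acc)
    expect_equal(acc[[best]], sort(acc, decreasing = TRUE)[[1L]])
    expect_equal(best, names(acc)[acc == max(acc)][1L])
  }
})

test_that("a single-member ensemble is that member", {
  d <- make_separable(n_per = 25L, p = 3L, gap = 4, seed = 18L)
  parts <- stratified_split(d, 0.6, 0.2, 0.2, seed = 11L)
  res <- run_edm(parts$train, parts$validation, parts$test,
                 members = list(eknn_member(n_c = 2L, max_iter = 20L)),
                 seed = 4L)
  expect_equal(res$best_method, "EKNN")
  m <- eknn(parts$train, n_c = 2L, max_iter = 20L,
            seed = dasd:::derive_seed(4L, 1L))
  expect_identical(res$test_predictions, predict(m, parts$test))
})

test_that("a perfect validation scorer is selected and failures are tolerated", {
  d <- make_separable(n_per = 25L, p = 3L, gap = 4, seed = 19L)
  parts <- stratified_split(d, 0.6, 0.2, 0.2, seed = 12L)
  # plant a validation set the constant classifier answers perfectly
  one_class_val <- parts$validation[parts$validation$labels == 1L, ]
  res <- suppressWarnings(  # constant predictions leave 0/0 test ratios
    run_edm(parts$train, one_class_val, parts$test,
            members = list(constant_member(1L), logistic_member()),
            seed = 5L))
  expect_equal(res$accuracy[["CONST"]], 1)
  expect_equal(res$best_method, "CONST")

  expect_warning(
    res2 <- run_edm(parts$train, parts$validation, parts$test,
                    members = list(failing_member(), logistic_member()),
                    seed = 5L),
    "BROKEN")
  expect_equal(res2$best_method, "LOGIT")
  expect_equal(res2$failed, "BROKEN")

  expect_error(
    suppressWarnings(run_edm(parts$train, parts$validation, parts$test,
                             members = list(failing_member()), seed = 5L)),
    "all ensemble members failed")
})

test_that("the default ensemble fits and its winner is at least as good as the weakest member", {
  gen <- generate_biomarkers(synthetic_spec(outlier_rate = 0, seed = 23L))
  parts <- stratified_split(gen$dataset, seed = 13L)
  members <- list(svm_member(), dla_member(size = 8L), eknn_member(max_iter = 50L))
  res <- run_edm(parts$train, parts$validation, parts$test,
                 members = members, seed = 6L)
  expect_setequal(names(res$accuracy), c("SVM", "DLA", "EKNN"))
  expect_equal(res$accuracy[[res$best_method]], max(res$accuracy))

  # winner's test accuracy is at least the worst member's test accuracy
  test_accs <- vapply(seq_along(members), function(j) {
    model <- members[[j]]$fit(parts$train, seed = dasd:::derive_seed(6L, j))
    mean(members[[j]]$predict(model, parts$test$values) == parts$test$labels)
  }, numeric(1))
  expect_gte(res$test_scores$accuracy, min(test_accs))
})
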