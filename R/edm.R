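#' Classifier contracts for the ensemble selector
#'
#' Each member of the ensemble is a small contract: a `name`, a
#' `fit(train, seed)` function returning an opaque model, and a
#' `predict(model, values)` function returning 0/1 labels. Three adapters are
#' provided over established implementations plus the package's own EKNN:
#'
#' * `svm_member()` — support vector machine, linear kernel with cost 16
#'   (via \pkg{e1071}).
#' * `dla_member()` — a single-hidden-layer feed-forward neural network
#'   (via \pkg{nnet}), the deep-learning member: 32 hidden units, weight
#'   decay 0.01.
#' * `logistic_member()` — logistic regression via `stats::glm`, a
#'   dependency-free fallback member.
#' * `eknn_member()` — the package's EKNN classifier; `...` is passed to
#'   [eknn()].
#'
#' @param cost SVM cost parameter. Default 16.
#' @param size,decay,maxit hidden units, weight decay and iteration cap of
#'   the neural-network member.
#' @param ... for `eknn_member()`, arguments forwarded to [eknn()].
#' @return A `classifier_contract` list with `name`, `fit`, `predict`.
#' @name edm_members
NULL

new_member <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "classifier_contract")
}

#' @rdname edm_members
#' @export
svm_member <- function(cost = 16) {
  new_member(
    "SVM",
    fit = function(train, seed = 1L) {
      set.seed(seed)
      e1071::svm(x = train$values, y = factor(train$labels, levels = c(0L, 1L)),
                 kernel = "linear", cost = cost, scale = TRUE)
    },
    predict = function(model, values) {
      as.integer(as.character(stats::predict(model, values)))
    }
  )
}

#' @rdname edm_members
#' @export
dla_member <- function(size = 32L, decay = 0.01, maxit = 200L) {
  new_member(
    "DLA",
    fit = function(train, seed = 1L) {
      set.seed(seed)
      center <- colMeans(train$values)
      scale <- apply(train$values, 2L, stats::sd)
      scale[scale == 0] <- 1
      z <- sweep(sweep(train$values, 2L, center), 2L, scale, "/")
      net <- nnet::nnet(z, train$labels, size = size, decay = decay,
                        maxit = maxit, entropy = TRUE, trace = FALSE,
                        MaxNWts = 100000L)
      list(net = net, center = center, scale = scale)
    },
    predict = function(model, values) {
      z <- sweep(sweep(values, 2L, model$center), 2L, model$scale, "/")
      as.integer(stats::predict(model$net, z) > 0.5)
    }
  )
}

#' @rdname edm_members
#' @export
logistic_member <- function() {
  new_member(
    "LOGIT",
    fit = function(train, seed = 1L) {
      df <- data.frame(y = train$labels, train$values, check.names = TRUE)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(model, values) {
      df <- data.frame(values, check.names = TRUE)
      p <- suppressWarnings(stats::predict(model, newdata = df, type = "response"))
      as.integer(p > 0.5)
    }
  )
}

#' @rdname edm_members
#' @export
eknn_member <- function(...) {
  args <- list(...)
  new_member(
    "EKNN",
    fit = function(train, seed = 1L) {
      do.call(eknn, c(list(x = train, seed = seed), args))
    },
    predict = function(model, values) {
      predict(model, values)
    }
  )
}

#' Select the best classifier by validation accuracy
#'
#' The ensemble's "majority voting" is a single-winner selection: the member
#' with the highest validation accuracy wins; ties are broken by position in
#' the member list (first wins).
#'
#' @param acc named numeric vector of validation accuracies, in member
#'   order.
#' @return The winning member's name.
#' @export
select_best <- function(acc) {
  if (length(acc) == 0L) stopf("empty accuracy map")
  names(acc)[which.max(acc)]
}

#' Run the ensemble diagnosis methodology (EDM)
#'
#' Fits every member contract on the training split, scores each on the
#' validation split, selects the winner with [select_best()], predicts the
#' test split with the winner, and reports the full confusion-matrix score
#' set. A member whose fit or validation fails is dropped with a warning;
#' the ensemble proceeds as long as one member remains.
#'
#' @param train,val,test [biomarker_dataset]s sharing the feature set.
#' @param members list of `classifier_contract`s; default SVM, DLA, EKNN.
#' @param seed integer seed forwarded (derived per member) to each fit.
#' @return An object of class `edm`: `accuracy` (named validation
#'   accuracies), `best_method`, `models` (fitted members),
#'   `test_predictions`, `test_scores` (from [classification_scores()]),
#'   `failed` (names of dropped members).
#' @export
run_edm <- function(train, val, test,
                    members = list(svm_member(), dla_member(), eknn_member()),
                    seed = 1L) {
  if (length(members) == 0L) stopf("need at least one member")
  models <- list()
  acc <- numeric(0)
  failed <- character(0)
  for (j in seq_along(members)) {
    m <- members[[j]]
    res <- tryCatch({
      model <- m$fit(train, seed = derive_seed(seed, j))
      pred <- m$predict(model, val$values)
      list(model = model, acc = mean(pred == val$labels))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warnf("member '%s' failed (%s); excluded", m$name, conditionMessage(res))
      failed <- c(failed, m$name)
      next
    }
    models[[m$name]] <- res$model
    acc[m$name] <- res$acc
  }
  if (length(acc) == 0L) stopf("all ensemble members failed")
  best <- select_best(acc)
  best_contract <- members[[which(vapply(members, `[[`, "", "name") == best)[1L]]]
  test_pred <- best_contract$predict(models[[best]], test$values)
  cm <- confusion_matrix(test$labels, test_pred)
  structure(
    list(accuracy = acc, best_method = best, models = models,
         test_predictions = test_pred, confusion = cm,
         test_scores = classification_scores(cm), failed = failed,
         members = members, seed = as.integer(seed)),
    class = "edm"
  )
}

#' @export
print.edm <- function(x, ...) {
  cat("Ensemble diagnosis (best-of validation accuracy)\n")
  for (nm in names(x$accuracy)) {
    marker <- if (nm == x$best_method) " <- selected" else ""
    cat(sprintf("  %-6s validation accuracy %.4f%s\n", nm, x$accuracy[nm], marker))
  }
  cat(sprintf("  test accuracy of %s: %.4f\n", x$best_method,
              x$test_scores$accuracy))
  invisible(x)
}
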