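#' Fit the full two-layer diagnostic pipeline
#'
#' Runs the data-filter layer then the diagnostic layer on a labeled
#' biomarker panel:
#'
#' 1. stratified train / validation / test split;
#' 2. binary grey wolf wrapper feature selection ([run_bgwo()]) on the
#'    training split, scored on the validation split;
#' 3. binary genetic algorithm outlier rejection ([run_bga()]) on the
#'    feature-filtered training rows;
#' 4. ensemble selection ([run_edm()]): every member classifier is fitted on
#'    the filtered training data, the best by validation accuracy predicts
#'    the test split.
#'
#' Either filter can be disabled, in which case the pipeline reduces to the
#' plain ensemble on the raw data. The whole run is reproducible: one master
#' seed drives derived seeds for the split, both filters and every member
#' fit, and all resolved settings are recorded in the returned object.
#'
#' @param x a [biomarker_dataset], or a feature matrix with `y` labels.
#' @param y integer 0/1 labels when `x` is a matrix.
#' @param members ensemble member contracts; default SVM, DLA, EKNN
#'   (see [edm_members]).
#' @param select_features,reject_outliers logical switches for the two
#'   filter stages. Default `TRUE`.
#' @param split fractions `c(train, validation, test)`. Default
#'   `c(0.6, 0.2, 0.2)`.
#' @param bgwo,bga named lists of extra arguments for [run_bgwo()] /
#'   [run_bga()] (e.g. `list(max_iter = 50)`).
#' @param seed master integer seed.
#' @param ... ignored.
#' @return An object of class `dasd`: `feature_mask`, `sample_mask`, `edm`
#'   (the fitted [run_edm()] result), `split` indices, `scores` on the test
#'   split, and `log` (resolved parameters and derived seeds).
#' @export
dasd <- function(x, ...) UseMethod("dasd")

#' @rdname dasd
#' @param formula a formula such as `label ~ .` naming the label column.
#' @param data a data.frame holding features and the label column.
#' @export
dasd.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y_raw <- stats::model.response(mf)
  lev <- sort(unique(as.character(y_raw)))
  if (length(lev) != 2L) stopf("response must have exactly 2 classes")
  pos <- if ("ASD" %in% lev) "ASD" else lev[2L]
  d <- biomarker_dataset(as.matrix(mf[, -1L, drop = FALSE]),
                         as.integer(as.character(y_raw) == pos),
                         classes = c(setdiff(lev, pos), pos))
  fit <- dasd.biomarker_dataset(d, ...)
  fit$formula <- formula
  fit
}

#' @rdname dasd
#' @export
dasd.default <- function(x, y, ...) {
  dasd.biomarker_dataset(biomarker_dataset(as.matrix(x), y), ...)
}

#' @rdname dasd
#' @export
dasd.biomarker_dataset <- function(x, members = NULL,
                                   select_features = TRUE,
                                   reject_outliers = TRUE,
                                   split = c(0.6, 0.2, 0.2),
                                   bgwo = list(), bga = list(),
                                   seed = 1L, ...) {
  members <- members %||% list(svm_member(), dla_member(), eknn_member())
  seeds <- list(split = derive_seed(seed, 1L), bgwo = derive_seed(seed, 2L),
                bga = derive_seed(seed, 3L), edm = derive_seed(seed, 4L))
  parts <- stratified_split(x, split[1L], split[2L], split[3L],
                            seed = seeds$split)
  train <- parts$train
  val <- parts$validation
  test <- parts$test

  feature_mask <- rep(TRUE, length(x$feature_names))
  names(feature_mask) <- x$feature_names
  bgwo_fit <- NULL
  if (select_features) {
    feature_mask <- do.call(run_bgwo, c(list(train = train, val = val,
                                             seed = seeds$bgwo), bgwo))
    bgwo_fit <- attr(feature_mask, "fitness")
    train <- train[, as.logical(feature_mask)]
    val <- val[, as.logical(feature_mask)]
    test <- test[, as.logical(feature_mask)]
  }

  sample_mask <- rep(TRUE, length(train$labels))
  names(sample_mask) <- train$sample_ids
  bga_fit <- NULL
  if (reject_outliers) {
    sample_mask <- do.call(run_bga, c(list(train = train, val = val,
                                           seed = seeds$bga), bga))
    bga_fit <- attr(sample_mask, "fitness")
    train <- train[as.logical(sample_mask), ]
  }

  edm_fit <- run_edm(train, val, test, members = members, seed = seeds$edm)
  structure(
    list(feature_mask = feature_mask, sample_mask = sample_mask,
         edm = edm_fit, split = parts$indices,
         scores = edm_fit$test_scores, classes = x$classes,
         log = list(seed = seed, seeds = seeds, split_fractions = split,
                    select_features = select_features,
                    reject_outliers = reject_outliers,
                    bgwo = c(list(fitness = bgwo_fit), bgwo),
                    bga = c(list(fitness = bga_fit), bga),
                    n_samples = length(x$labels),
                    n_features = length(x$feature_names),
                    n_features_kept = sum(feature_mask),
                    n_train_kept = sum(sample_mask),
                    members = vapply(members, `[[`, "", "name"))),
    class = "dasd"
  )
}

#' @export
print.dasd <- function(x, ...) {
  cat("Two-layer diagnostic pipeline (filter layer + diagnostic layer)\n")
  cat(sprintf("  features kept: %d of %d; training rows kept: %d of %d\n",
              sum(x$feature_mask), length(x$feature_mask),
              sum(x$sample_mask), length(x$sample_mask)))
  cat(sprintf("  selected diagnostic method: %s\n", x$edm$best_method))
  cat(sprintf("  test accuracy: %.4f (error %.4f)\n",
              x$scores$accuracy, x$scores$error))
  invisible(x)
}

#' @export
summary.dasd <- function(object, ...) {
  print(object)
  cat("  validation accuracy by member:\n")
  for (nm in names(object$edm$accuracy)) {
    cat(sprintf("    %-6s %.4f\n", nm, object$edm$accuracy[nm]))
  }
  s <- object$scores
  cat(sprintf(paste0("  test scores: precision %.4f, recall %.4f, ",
                     "macro-P %.4f, macro-R %.4f, F1 %.4f\n"),
              s$precision, s$recall, s$macro_precision, s$macro_recall, s$f1))
  invisible(object)
}

#' Predict with a fitted pipeline
#'
#' Applies the stored feature mask and the selected diagnostic method to new
#' samples.
#'
#' @param object a fitted [dasd] pipeline.
#' @param newdata feature matrix (full, unfiltered feature set) or
#'   [biomarker_dataset].
#' @param type `"encoded"` (default) or `"class"`.
#' @param ... ignored.
#' @return Predicted labels.
#' @export
predict.dasd <- function(object, newdata, type = c("encoded", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "biomarker_dataset")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$feature_mask)) {
    stopf("newdata has %d features; pipeline expects %d", ncol(newdata),
          length(object$feature_mask))
  }
  vals <- newdata[, as.logical(object$feature_mask), drop = FALSE]
  best <- object$edm$best_method
  contract <- object$edm$members[[
    which(vapply(object$edm$members, `[[`, "", "name") == best)[1L]]]
  pred <- contract$predict(object$edm$models[[best]], vals)
  if (type == "class") object$classes[pred + 1L] else as.integer(pred)
}
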