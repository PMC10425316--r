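#' Fit an enhanced K-nearest-neighbor (EKNN) classifier
#'
#' EKNN chains three stages: (1) a naive-Bayes weighting that maps samples
#' from feature space into a bounded per-class weight space
#' ([fit_weighting()]); (2) chimp-optimization prototype generation
#' ([run_coa()]) that compresses the weighted training set into `n_c`
#' artificial "New-cases" per class; (3) K-nearest-neighbor prediction over
#' the New-cases. The prototype set is strictly smaller than the training
#' set, which is what makes prediction fast.
#'
#' @param x feature matrix (samples x features), or a [biomarker_dataset]
#'   (in which case `y` is ignored).
#' @param y integer 0/1 labels (1 = positive class).
#' @param k neighbors used for prediction (and inside the COA fitness).
#'   Default 3, the value that minimizes validation error on this family of
#'   panels.
#' @param n_c New-cases generated per class. Default 3.
#' @param population_size,max_iter COA search budget. Defaults 20 and 100.
#' @param reduce if `FALSE`, skip prototype generation and use the full
#'   weighted training set as the reference set (the reduction-free
#'   weighted-KNN limit). Default `TRUE`.
#' @param weight if `FALSE`, skip the naive-Bayes weighting and work on
#'   z-scored raw features (the plain-KNN baseline). Default `TRUE`.
#' @param seed integer seed; fitting is deterministic given it.
#' @param ... passed on to [coa_config()].
#' @return An object of class `eknn` with fields `weighting`, `prototypes`
#'   (reference matrix), `proto_labels`, `k`, `classes` and `coa` (fitness
#'   history, when reduction ran).
#' @export
eknn <- function(x, ...) UseMethod("eknn")

#' @rdname eknn
#' @export
eknn.biomarker_dataset <- function(x, y = NULL, ...) {
  eknn.default(x$values, x$labels, classes = x$classes, ...)
}

#' @rdname eknn
#' @param formula a formula such as `label ~ .` naming the label column.
#' @param data a data.frame holding features and the label column.
#' @export
eknn.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y_raw <- stats::model.response(mf)
  feats <- mf[, -1L, drop = FALSE]
  if (is.character(y_raw) || is.factor(y_raw)) {
    lev <- sort(unique(as.character(y_raw)))
    if (length(lev) != 2L) stopf("response must have exactly 2 classes")
    pos <- if ("ASD" %in% lev) "ASD" else lev[2L]
    y <- as.integer(as.character(y_raw) == pos)
    classes <- c(setdiff(lev, pos), pos)
  } else {
    y <- as.integer(y_raw)
    classes <- c("0", "1")
  }
  fit <- eknn.default(as.matrix(feats), y, classes = classes, ...)
  fit$formula <- formula
  fit
}

#' @rdname eknn
#' @param classes length-2 character vector `c(negative, positive)`.
#' @export
eknn.default <- function(x, y, k = 3L, n_c = 3L, population_size = 20L,
                         max_iter = 100L, reduce = TRUE, weight = TRUE,
                         seed = 1L, classes = c("TD", "ASD"), ...) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!is_count(k)) stopf("k must be a positive integer")
  d <- biomarker_dataset(x, y, classes = classes)
  w <- fit_weighting(d)
  train_w <- if (weight) to_weight_space(w, x) else
    sweep(sweep(x, 2L, w$center), 2L, w$scale, "/")

  coa_info <- NULL
  if (reduce) {
    cfg <- coa_config(A = ncol(train_w), n_c = n_c, y_d = 2L, k = k,
                      population_size = population_size,
                      max_iter = max_iter, seed = derive_seed(seed, 11L),
                      bounds = if (weight) NULL else
                        list(lo = apply(train_w, 2L, min),
                             hi = apply(train_w, 2L, max)),
                      ...)
    ps <- run_coa(train_w, y, cfg)
    protos <- ps$prototypes
    proto_labels <- ps$labels
    coa_info <- list(fitness = attr(ps, "fitness"),
                     history = attr(ps, "history"), config = cfg)
  } else {
    protos <- train_w
    proto_labels <- y
  }
  structure(
    list(weighting = w, prototypes = protos, proto_labels = proto_labels,
         k = as.integer(k), weight = weight, classes = as.character(classes),
         n_train = nrow(x), coa = coa_info, seed = as.integer(seed)),
    class = "eknn"
  )
}

#' Predict with a fitted EKNN classifier
#'
#' Maps the query samples into the model's weight space and assigns the
#' majority label of the `k` nearest prototypes (Euclidean distance);
#' distance ties go to the lower-index prototype and an even vote split to
#' the nearest prototype's label.
#'
#' @param object a fitted [eknn] model.
#' @param newdata feature matrix, single feature vector, data.frame or
#'   [biomarker_dataset].
#' @param type `"encoded"` (default) for integer 0/1 labels or `"class"` for
#'   class names.
#' @param ... ignored.
#' @return Predicted labels.
#' @export
predict.eknn <- function(object, newdata, type = c("encoded", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "biomarker_dataset")) newdata <- newdata$values
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$weighting$feature_names, drop = FALSE])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$weighting$feature_names)) {
    stopf("newdata has %d features; model expects %d", ncol(newdata),
          length(object$weighting$feature_names))
  }
  q <- if (object$weight) to_weight_space(object$weighting, newdata) else
    sweep(sweep(newdata, 2L, object$weighting$center), 2L,
          object$weighting$scale, "/")
  pred <- knn_predict(object$prototypes, object$proto_labels, q, object$k)
  if (type == "class") object$classes[pred + 1L] else pred
}

#' @export
print.eknn <- function(x, ...) {
  cat("Enhanced KNN classifier (NB weighting + COA prototypes + KNN)\n")
  cat(sprintf("  trained on %d cases; %d prototypes (%s); k = %d\n",
              x$n_train, nrow(x$prototypes),
              if (is.null(x$coa)) "reduction-free" else "COA-generated", x$k))
  if (!is.null(x$coa)) {
    cat(sprintf("  COA training fitness: %.4f\n", x$coa$fitness))
  }
  invisible(x)
}

#' @export
summary.eknn <- function(object, ...) {
  print(object)
  cat(sprintf("  classes: %s (0), %s (1); weight space: %s\n",
              object$classes[1L], object$classes[2L],
              if (object$weight) "NB normalized evidence" else "z-scored features"))
  if (!is.null(object$coa)) {
    h <- object$coa$history
    cat(sprintf("  COA fitness: start %.4f -> final %.4f over %d iterations\n",
                h[1L], h[length(h)], length(h) - 1L))
  }
  invisible(object)
}

#' Serialize / restore an EKNN model as JSON
#'
#' Round-trips every component needed for prediction (weighting parameters,
#' prototypes, labels, `k`) through a JSON file, so a fitted model can be
#' checkpointed and reloaded with identical predictions.
#'
#' @param object a fitted [eknn] model.
#' @param path JSON file path.
#' @return `path` (write) / the restored `eknn` object (read).
#' @export
write_eknn <- function(object, path) {
  stopifnot(inherits(object, "eknn"))
  payload <- list(
    weighting = list(center = object$weighting$center,
                     scale = object$weighting$scale,
                     mu = object$weighting$mu, sigma = object$weighting$sigma,
                     priors = object$weighting$priors,
                     feature_names = object$weighting$feature_names,
                     classes = object$weighting$classes),
    prototypes = object$prototypes, proto_labels = object$proto_labels,
    k = object$k, weight = object$weight, classes = object$classes,
    n_train = object$n_train, seed = object$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eknn
#' @export
read_eknn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- structure(list(
    center = stats::setNames(as.numeric(p$weighting$center),
                             p$weighting$feature_names),
    scale = stats::setNames(as.numeric(p$weighting$scale),
                            p$weighting$feature_names),
    mu = as.matrix(p$weighting$mu), sigma = as.matrix(p$weighting$sigma),
    priors = as.numeric(p$weighting$priors),
    feature_names = p$weighting$feature_names,
    classes = p$weighting$classes), class = "weight_mapping")
  structure(
    list(weighting = w, prototypes = as.matrix(p$prototypes),
         proto_labels = as.integer(p$proto_labels), k = as.integer(p$k),
         weight = as.logical(p$weight), classes = p$classes,
         n_train = as.integer(p$n_train), coa = NULL,
         seed = as.integer(p$seed)),
    class = "eknn"
  )
}

#' Select the neighbor count by validation error
#'
#' Evaluates the weighted-KNN classifier for every `k` in `k_range` and
#' returns the value minimizing validation error; ties go to the smallest
#' `k`.
#'
#' @param train,val [biomarker_dataset]s.
#' @param k_range candidate neighbor counts. Default `1:5`.
#' @return The selected `k`, with attribute `errors` (validation error per
#'   candidate).
#' @export
select_k <- function(train, val, k_range = 1:5) {
  if (length(k_range) == 0L) stopf("empty k_range")
  errors <- vapply(k_range, function(kk) {
    pred <- weighted_knn(train, val$values, k = kk)
    mean(pred != val$labels)
  }, numeric(1L))
  best <- k_range[order(errors, k_range)[1L]]
  attr(best, "errors") <- stats::setNames(errors, k_range)
  best
}
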