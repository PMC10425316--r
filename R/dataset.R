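#' Biomarker dataset container
#'
#' A light container for a samples x features table of continuous biomarker
#' measurements with a binary class label. Labels are stored encoded as
#' integers, 1 for the positive class (cases, e.g. "ASD") and 0 for the
#' negative class (controls, e.g. "TD"); the original class names are kept in
#' the `classes` field, ordered `c(negative, positive)`.
#'
#' @param values numeric matrix, one row per sample, one column per feature.
#' @param labels integer (or coercible) vector of 0/1 labels, or a character /
#'   factor vector of class names (mapped via `classes`).
#' @param feature_names character vector of feature names; defaults to the
#'   column names of `values`.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   row names of `values` or `"S1"`, `"S2"`, ...
#' @param classes length-2 character vector `c(negative, positive)` naming the
#'   two classes. Defaults to `c("TD", "ASD")`.
#' @return An object of class `biomarker_dataset` with fields `values`,
#'   `labels`, `feature_names`, `sample_ids`, `classes`.
#' @export
biomarker_dataset <- function(values, labels, feature_names = NULL,
                              sample_ids = NULL, classes = c("TD", "ASD")) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stopf("missing value in row %d, column %d", bad[1L], bad[2L])
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    unknown <- setdiff(unique(labels), classes)
    if (length(unknown) > 0L) {
      stopf("label(s) %s not in declared classes (%s)",
            paste(unknown, collapse = ", "), paste(classes, collapse = ", "))
    }
    labels <- as.integer(labels == classes[2L])
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be encoded 0/1")
  if (length(labels) != nrow(values)) {
    stopf("length(labels) [%d] != number of rows [%d]", length(labels), nrow(values))
  }
  feature_names <- feature_names %||% colnames(values) %||%
    sprintf("F%02d", seq_len(ncol(values)))
  sample_ids <- sample_ids %||% rownames(values) %||%
    sprintf("S%d", seq_len(nrow(values)))
  if (length(feature_names) != ncol(values)) stopf("feature_names length mismatch")
  if (length(sample_ids) != nrow(values)) stopf("sample_ids length mismatch")
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, labels = labels,
         feature_names = as.character(feature_names),
         sample_ids = as.character(sample_ids),
         classes = as.character(classes)),
    class = "biomarker_dataset"
  )
}

#' @export
print.biomarker_dataset <- function(x, ...) {
  cat(sprintf("<biomarker_dataset> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  classes: %s (0) = %d, %s (1) = %d\n",
              x$classes[1L], sum(x$labels == 0L),
              x$classes[2L], sum(x$labels == 1L)))
  invisible(x)
}

#' @export
dim.biomarker_dataset <- function(x) dim(x$values)

#' Subset a biomarker dataset
#'
#' @param x a [biomarker_dataset].
#' @param i sample index (integer, logical, or character ids).
#' @param j feature index (integer, logical, or character names).
#' @param ... ignored.
#' @return The subsetted `biomarker_dataset`.
#' @export
`[.biomarker_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$feature_names)
  biomarker_dataset(x$values[i, j, drop = FALSE], x$labels[i],
                    x$feature_names[j], x$sample_ids[i], x$classes)
}

#' Read a biomarker table from delimited text
#'
#' Reads a CSV/TSV file with a header row, one labeled column and numeric
#' feature columns. The positive class is encoded as 1 and the negative class
#' as 0. Missing values, non-numeric feature cells, or a label column with a
#' number of distinct values other than two are hard errors.
#'
#' @param path path to a delimited text file.
#' @param label_column name of the label column. Default `"label"`.
#' @param positive name of the positive class. Defaults to `"ASD"` when
#'   present among the labels, otherwise the lexicographically later value.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param id_column optional name of a sample-id column.
#' @return A [biomarker_dataset].
#' @export
read_biomarkers <- function(path, label_column = "label", positive = NULL,
                            sep = ",", id_column = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stopf("label column '%s' not found in %s", label_column, path)
  }
  lab_raw <- as.character(df[[label_column]])
  lev <- sort(unique(lab_raw))
  if (length(lev) != 2L) {
    stopf("label column '%s' has %d distinct values (need exactly 2): %s",
          label_column, length(lev), paste(lev, collapse = ", "))
  }
  positive <- positive %||% (if ("ASD" %in% lev) "ASD" else lev[2L])
  if (!positive %in% lev) stopf("positive class '%s' not among labels", positive)
  negative <- setdiff(lev, positive)
  ids <- NULL
  drop <- label_column
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stopf("id column '%s' not found", id_column)
    ids <- as.character(df[[id_column]])
    drop <- c(drop, id_column)
  }
  feat <- df[, setdiff(names(df), drop), drop = FALSE]
  for (nm in names(feat)) {
    col <- feat[[nm]]
    if (anyNA(col)) {
      stopf("missing value in column '%s', row %d", nm, which(is.na(col))[1L])
    }
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num)) {
        stopf("non-numeric value in column '%s', row %d", nm, which(is.na(num))[1L])
      }
      feat[[nm]] <- num
    }
  }
  biomarker_dataset(as.matrix(feat), lab_raw, names(feat), ids,
                    classes = c(negative, positive))
}

#' Write a biomarker dataset to delimited text
#'
#' The inverse of [read_biomarkers()]: writes one row per sample with an `id`
#' column, the feature columns at full precision, and a `label` column holding
#' the class names.
#'
#' @param d a [biomarker_dataset].
#' @param path output file path.
#' @param sep field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(d, path, sep = ",") {
  df <- data.frame(id = d$sample_ids, d$values,
                   label = d$classes[d$labels + 1L],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", d$feature_names, "label")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Largest-remainder allocation of n items to parts with the given fractions.
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified three-way split
#'
#' Partitions a dataset into train / validation / test parts, stratified by
#' class: within each class the samples are shuffled and allocated by
#' largest-remainder quotas, so each part's class proportion is within one
#' sample of the global proportion and the three parts form an exact
#' partition.
#'
#' @param d a [biomarker_dataset].
#' @param train,validation,test fractions in `[0, 1]` summing to 1.
#'   Default 0.6 / 0.2 / 0.2.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return A list with elements `train`, `validation`, `test`
#'   (each a `biomarker_dataset`) and `indices` (the corresponding row
#'   indices into `d`).
#' @export
stratified_split <- function(d, train = 0.6, validation = 0.2, test = 0.2,
                             seed = 1L) {
  fr <- c(train, validation, test)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8) {
    stopf("fractions must lie in [0,1] and sum to 1")
  }
  n_parts <- sum(fr > 0)
  idx <- list(integer(0), integer(0), integer(0))
  set.seed(seed)
  for (cl in c(0L, 1L)) {
    cls_idx <- which(d$labels == cl)
    if (length(cls_idx) < n_parts) {
      stopf("class %d has %d samples, fewer than the %d requested parts",
            cl, length(cls_idx), n_parts)
    }
    cls_idx <- sample(cls_idx)
    counts <- allocate_counts(length(cls_idx), fr)
    at <- cumsum(c(0L, counts))
    for (p in 1:3) {
      if (counts[p] > 0) {
        idx[[p]] <- c(idx[[p]], cls_idx[(at[p] + 1L):at[p + 1L]])
      }
    }
  }
  idx <- lapply(idx, sort)
  list(train = d[idx[[1L]], ], validation = d[idx[[2L]], ],
       test = d[idx[[3L]], ],
       indices = list(train = idx[[1L]], validation = idx[[2L]], test = idx[[3L]]))
}

#' Stratified k-fold cross-validation indices
#'
#' Partitions the sample indices into `folds` test sets of near-equal size
#' (differing by at most one), stratified by class; the complementary indices
#' form each training set.
#'
#' @param d a [biomarker_dataset].
#' @param folds integer number of folds, default 10.
#' @param seed integer seed.
#' @return A list of `folds` elements, each `list(train =, test =)` of integer
#'   row indices into `d`.
#' @export
kfold_indices <- function(d, folds = 10L, seed = 1L) {
  n <- nrow(d$values)
  if (!is_count(folds, min = 2L)) stopf("folds must be an integer >= 2")
  if (folds > n) stopf("folds (%d) exceeds number of samples (%d)", folds, n)
  set.seed(seed)
  assignment <- integer(n)
  offset <- 0L
  for (cl in c(0L, 1L)) {
    cls_idx <- which(d$labels == cl)
    cls_idx <- sample(cls_idx)
    # round-robin with a rotating offset so fold sizes stay balanced overall
    assignment[cls_idx] <- ((seq_along(cls_idx) - 1L + offset) %% folds) + 1L
    offset <- offset + length(cls_idx)
  }
  lapply(seq_len(folds), function(f) {
    test <- which(assignment == f)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
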