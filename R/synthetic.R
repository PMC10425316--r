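#' Specification for a synthetic biomarker panel
#'
#' Describes a samples x features panel with planted structure: a subset of
#' informative features whose class-conditional means differ by a chosen
#' standardized effect, irrelevant noise features identically distributed in
#' both classes, and a fraction of corrupted training rows. Defaults mirror
#' the cohort shape the pipeline was designed around: 154 children
#' (76 cases / 78 controls) measured on a 50-protein panel of which 15
#' proteins carry signal, with 10% corrupted rows.
#'
#' @param n_samples total number of samples. Default 154.
#' @param class_sizes integer pair `c(positive, negative)` summing to
#'   `n_samples`. Default `c(76, 78)` (76 "ASD", 78 "TD").
#' @param n_informative number of informative features. Default 15.
#' @param n_noise number of irrelevant features. Default 35.
#' @param effect_size standardized mean shift of each informative feature
#'   between classes (per-feature Cohen's d). Default 2.
#' @param outlier_rate fraction of rows corrupted, in `[0, 1)`. Default 0.1.
#' @param outlier_mode `"feature_corrupt"` (default): every feature of a
#'   corrupted row is redrawn far outside the clean range, uniformly in
#'   `[mu + 6*sd, mu + 10*sd]` of that feature's clean class-conditional
#'   distribution; or `"label_flip"`: the row keeps clean values but its
#'   label is flipped.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 154L, class_sizes = c(76L, 78L),
                           n_informative = 15L, n_noise = 35L,
                           effect_size = 2, outlier_rate = 0.1,
                           outlier_mode = c("feature_corrupt", "label_flip"),
                           seed = 1L) {
  outlier_mode <- match.arg(outlier_mode)
  if (sum(class_sizes) != n_samples) stopf("class_sizes must sum to n_samples")
  if (any(class_sizes <= 0) || n_informative < 0 || n_noise < 0) {
    stopf("counts must be non-negative and class sizes positive")
  }
  if (n_informative + n_noise < 1) stopf("need at least one feature")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (outlier_rate < 0 || outlier_rate >= 1) stopf("outlier_rate must lie in [0, 1)")
  structure(
    list(n_samples = as.integer(n_samples),
         class_sizes = as.integer(class_sizes),
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise),
         effect_size = effect_size, outlier_rate = outlier_rate,
         outlier_mode = outlier_mode, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic biomarker panel with ground truth
#'
#' Draws informative features from class-conditional Gaussians
#' `N(0, 1)` (negative class) and `N(effect_size, 1)` (positive class), noise
#' features from `N(0, 1)` in both classes, then corrupts a fraction of rows
#' per the spec's `outlier_mode`. The returned ground truth records which
#' features are informative and which rows were corrupted, so feature
#' selection and outlier rejection can be scored against a known answer.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `dataset` (a [biomarker_dataset]) and `truth`, a list
#'   with `informative_mask` (logical per feature) and `outlier_mask`
#'   (logical per sample).
#' @export
generate_biomarkers <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  p <- spec$n_informative + spec$n_noise
  labels <- rep(c(1L, 0L), spec$class_sizes)
  mu <- matrix(0, nrow = n, ncol = p)
  if (spec$n_informative > 0) {
    mu[labels == 1L, seq_len(spec$n_informative)] <- spec$effect_size
  }
  values <- mu + matrix(stats::rnorm(n * p), nrow = n, ncol = p)

  n_out <- as.integer(round(spec$outlier_rate * n))
  outlier_mask <- rep(FALSE, n)
  if (n_out > 0) {
    out_idx <- sort(sample.int(n, n_out))
    outlier_mask[out_idx] <- TRUE
    if (spec$outlier_mode == "label_flip") {
      labels[out_idx] <- 1L - labels[out_idx]
    } else {
      for (i in out_idx) {
        # clean sd is 1 per feature; mu is the row's class-conditional mean
        values[i, ] <- mu[i, ] + stats::runif(p, min = 6, max = 10)
      }
    }
  }
  feature_names <- sprintf("BM%02d", seq_len(p))
  d <- biomarker_dataset(values, labels, feature_names,
                         sprintf("S%03d", seq_len(n)))
  truth <- list(
    informative_mask = seq_len(p) <= spec$n_informative,
    outlier_mask = outlier_mask
  )
  list(dataset = d, truth = truth)
}
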