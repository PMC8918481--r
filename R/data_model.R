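#' Labeled binary-class dataset
#'
#' The carrier object passed between every stage of the pipeline: an `n x d`
#' numeric feature matrix plus a binary label vector. By package convention
#' label `1` is the MINORITY (positive) class — the class of interest in
#' imbalanced classification — and all AUC values are oriented towards it.
#'
#' @param features Numeric matrix (`n x d`) of finite values. A data frame of
#'   numeric columns is accepted and converted.
#' @param labels Vector of length `n` with values in `{0, 1}`.
#' @param feature_names Optional character vector of length `d`; defaults to
#'   the matrix column names or `f1..fd`.
#' @param require_both_classes If `TRUE`, error unless both classes are
#'   present (training stages need this; a scoring partition may not).
#' @return An object of class `labeled_dataset` with elements `features`,
#'   `labels` and `feature_names`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL,
                            require_both_classes = FALSE) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    imb_stop("imbfuse_format_error", "`features` must be a numeric matrix")
  }
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  if (n < 2L || d < 1L) {
    imb_stop("imbfuse_format_error",
             sprintf("need n >= 2 and d >= 1, got n = %d, d = %d", n, d))
  }
  if (!all(is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    imb_stop("imbfuse_format_error",
             sprintf("non-finite feature value at row %d, column %d",
                     bad[1L], bad[2L]))
  }
  labels <- as.integer(labels)
  if (length(labels) != n || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    imb_stop("imbfuse_format_error",
             "`labels` must be a length-n vector with values in {0, 1}")
  }
  if (require_both_classes && length(unique(labels)) < 2L) {
    imb_stop("imbfuse_single_class_error",
             "both classes must be present in a training dataset")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features) %||% paste0("f", seq_len(d))
  }
  if (length(feature_names) != d) {
    imb_stop("imbfuse_format_error", "`feature_names` must have length d")
  }
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- nrow(x$features)
  n1 <- sum(x$labels == 1L)
  cat(sprintf("labeled_dataset: %d samples x %d features\n", n,
              ncol(x$features)))
  cat(sprintf("  minority (label 1): %d, majority (label 0): %d, IR = %.2f\n",
              n1, n - n1, if (n1 > 0) (n - n1) / n1 else Inf))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

#' Subset a labeled dataset by row indices
#'
#' @param dataset A [labeled_dataset()].
#' @param idx Integer row indices to keep.
#' @return A `labeled_dataset` with the selected rows.
#' @export
dataset_subset <- function(dataset, idx) {
  labeled_dataset(dataset$features[idx, , drop = FALSE],
                  dataset$labels[idx],
                  feature_names = dataset$feature_names)
}

n_minority <- function(dataset) sum(dataset$labels == 1L)
n_majority <- function(dataset) sum(dataset$labels == 0L)

#' Specification for the synthetic imbalanced-data generator
#'
#' Describes a two-class Gaussian dataset: the majority class is an isotropic
#' unit-variance Gaussian at the origin of the informative subspace; the
#' minority class sits at distance `class_separation` (in within-class
#' standard-deviation units) along the first informative axis. Noise
#' dimensions are standard Gaussians for both classes and carry no class
#' signal. `n_majority / n_minority` is the imbalance ratio.
#'
#' @param n_majority,n_minority Class sizes; `n_majority >= n_minority >= 2`.
#' @param d_informative Number of informative dimensions (`>= 1`).
#' @param d_noise Number of pure-noise dimensions (`>= 0`).
#' @param class_separation Nonnegative distance between the class means.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_majority, n_minority, d_informative = 2L,
                           d_noise = 0L, class_separation = 3,
                           seed = 1L) {
  n_majority <- as.integer(n_majority)
  n_minority <- as.integer(n_minority)
  d_informative <- as.integer(d_informative)
  d_noise <- as.integer(d_noise)
  if (n_minority < 2L || n_majority < n_minority) {
    imb_stop("imbfuse_parameter_error",
             "need n_majority >= n_minority >= 2")
  }
  if (d_informative < 1L || d_noise < 0L) {
    imb_stop("imbfuse_parameter_error",
             "need d_informative >= 1 and d_noise >= 0")
  }
  if (!is.finite(class_separation) || class_separation < 0) {
    imb_stop("imbfuse_parameter_error",
             "`class_separation` must be a nonnegative real")
  }
  structure(list(n_majority = n_majority, n_minority = n_minority,
                 d_informative = d_informative, d_noise = d_noise,
                 class_separation = class_separation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic imbalanced two-class dataset
#'
#' Majority rows come first, then minority rows (label 1). Deterministic for
#' a fixed spec (including its seed); the caller's RNG state is untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_dataset()] with `n_majority + n_minority` rows and
#'   `d_informative + d_noise` columns.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$d_informative + spec$d_noise
  n <- spec$n_majority + spec$n_minority
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    min_rows <- spec$n_majority + seq_len(spec$n_minority)
    x[min_rows, 1L] <- x[min_rows, 1L] + spec$class_separation
    labels <- c(rep(0L, spec$n_majority), rep(1L, spec$n_minority))
    labeled_dataset(x, labels,
                    feature_names = paste0("f", seq_len(d)))
  })
}

#' Stratified K-fold assignment
#'
#' Assigns every sample to exactly one of `K` folds so that each fold's class
#' proportions match the global proportions to within one sample per class.
#' Within each class, indices are shuffled under the given seed and dealt
#' round-robin, so remainder samples land on folds in shuffled order.
#'
#' @param dataset A [labeled_dataset()].
#' @param K Number of folds; each class must have at least `K` samples.
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: a list with `fold_index`
#'   (length-n integers in `1..K`) and `K`.
#' @export
stratified_folds <- function(dataset, K, seed = 1L) {
  K <- as.integer(K)
  if (K < 2L) imb_stop("imbfuse_parameter_error", "need K >= 2")
  fold_index <- integer(length(dataset$labels))
  for (cls in c(0L, 1L)) {
    idx <- which(dataset$labels == cls)
    if (length(idx) < K) {
      imb_stop("imbfuse_stratification_error",
               sprintf("class %d has %d samples; cannot stratify into %d folds",
                       cls, length(idx), K))
    }
    shuffled <- with_seed(derive_seed(seed, 71L, cls), sample(idx))
    fold_index[shuffled] <- rep_len(seq_len(K), length(idx))
  }
  structure(list(fold_index = fold_index, K = K),
            class = "fold_assignment")
}

#' Stratified train/validation split
#'
#' Holds out approximately `fraction` of each class (at least one sample per
#' class, never the whole class), shuffled under the seed.
#'
#' @param dataset A [labeled_dataset()].
#' @param fraction Fraction in (0, 1) to hold out.
#' @param seed Integer seed.
#' @return List with integer index vectors `fit` and `holdout`.
#' @export
stratified_split <- function(dataset, fraction = 0.25, seed = 1L) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    imb_stop("imbfuse_parameter_error", "`fraction` must lie in (0, 1)")
  }
  holdout <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(dataset$labels == cls)
    n_hold <- min(length(idx) - 1L, max(1L, round(fraction * length(idx))))
    shuffled <- with_seed(derive_seed(seed, 73L, cls), sample(idx))
    holdout <- c(holdout, shuffled[seq_len(n_hold)])
  }
  holdout <- sort(holdout)
  list(fit = setdiff(seq_along(dataset$labels), holdout), holdout = holdout)
}
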