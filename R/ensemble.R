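# Random feature-subspace ensemble over the transformed data. Each of the N
# members sees a random M-subset of the transformed columns
# (M = max(1, floor(feature_ratio * r))), trains on a SMOTE-balanced copy of
# its projection, and contributes a score column; the ensemble prediction is
# the weighted sum of member scores.

#' Draw random feature subspaces
#'
#' Each subspace is a uniform random `M`-subset of the `r` transformed
#' feature columns, drawn without replacement within a subspace and
#' independently across subspaces (overlap and repeats across subspaces are
#' allowed). `M = max(1, floor(feature_ratio * r))`.
#'
#' @param r Transformed feature dimension.
#' @param feature_ratio Fraction of features per subspace, in `(0, 1]`.
#' @param n_subspaces Number of subspaces `N` (`>= 1`).
#' @param seed Integer seed; draws are deterministic per seed.
#' @return List of `N` strictly increasing integer index vectors.
#' @export
sample_subspaces <- function(r, feature_ratio = 0.7, n_subspaces = 15L,
                             seed = 1L) {
  r <- as.integer(r)
  n_subspaces <- as.integer(n_subspaces)
  if (n_subspaces < 1L) {
    imb_stop("imbfuse_parameter_error", "`n_subspaces` must be >= 1")
  }
  if (!is.finite(feature_ratio) || feature_ratio <= 0 || feature_ratio > 1) {
    imb_stop("imbfuse_parameter_error", "`feature_ratio` must lie in (0, 1]")
  }
  m <- max(1L, as.integer(floor(feature_ratio * r)))
  with_seed(seed, {
    lapply(seq_len(n_subspaces), function(i) sort(sample.int(r, m)))
  })
}

#' Full-pipeline configuration
#'
#' Bundles every tunable of the adaptive-fusion pipeline. Defaults follow
#' the evaluation protocol: 15 subspaces, feature ratio 0.7, linear
#' max-margin base classifier, ImLMNN transform, GA-optimized voting
#' weights fitted on an internal stratified validation split.
#'
#' @param transform `"imlmnn"` (imbalance-weighted metric learning),
#'   `"lmnn"` (unweighted baseline) or `"none"` (identity map; ablation).
#' @param n_subspaces Number of ensemble members `N`.
#' @param feature_ratio Fraction of transformed features per subspace.
#' @param imlmnn An [imlmnn_config()] for the transform stage.
#' @param smote_k SMOTE neighbor count per seed sample.
#' @param classifier A `base_classifier` contract object.
#' @param ga A [ga_config()] for the weight search.
#' @param use_ga If `FALSE`, keep uniform voting weights (no internal split).
#' @param ga_fraction Fraction of the training partition held out (stratified)
#'   for the GA's AUC fitness; that slice is excluded from metric learning
#'   and member training.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(transform = c("imlmnn", "lmnn", "none"),
                            n_subspaces = 15L, feature_ratio = 0.7,
                            imlmnn = imlmnn_config(), smote_k = 5L,
                            classifier = linear_svm_classifier(),
                            ga = ga_config(), use_ga = TRUE,
                            ga_fraction = 0.25, seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(inherits(classifier, "base_classifier"))
  structure(list(transform = transform,
                 n_subspaces = as.integer(n_subspaces),
                 feature_ratio = feature_ratio, imlmnn = imlmnn,
                 smote_k = as.integer(smote_k), classifier = classifier,
                 ga = ga, use_ga = isTRUE(use_ga),
                 ga_fraction = ga_fraction, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Train the subspace ensemble (uniform weights)
#'
#' Fits the configured transform on `train`, maps the data, draws
#' `n_subspaces` random subspaces, and per member: projects to the subspace,
#' SMOTE-balances the projection, and fits a fresh base classifier. Voting
#' weights start uniform; [fit_pipeline()] replaces them with GA-optimized
#' weights. Member seeds are derived deterministically from `config$seed`.
#'
#' @param train A [labeled_dataset()] with both classes present.
#' @param config An [ensemble_config()].
#' @return An object of class `ensemble_model` with elements `transform`,
#'   `subspaces`, `members`, `weights`, `classifier`, `config`.
#' @export
train_ensemble <- function(train, config = ensemble_config()) {
  transform <- switch(config$transform,
    imlmnn = fit_imlmnn(train, config$imlmnn),
    lmnn = fit_lmnn(train, config$imlmnn),
    none = identity_transform(train, config$imlmnn$standardize))
  z <- apply_transform(transform, train)
  r <- ncol(z$features)
  subspaces <- sample_subspaces(r, config$feature_ratio, config$n_subspaces,
                                seed = derive_seed(config$seed, 11L))
  members <- vector("list", config$n_subspaces)
  for (i in seq_len(config$n_subspaces)) {
    res <- tryCatch({
      sub <- labeled_dataset(z$features[, subspaces[[i]], drop = FALSE],
                             z$labels)
      bal <- smote_balance(sub, smote_params(config$smote_k,
                                             derive_seed(config$seed, 13L, i)))
      config$classifier$fit(bal$features, bal$labels,
                            seed = derive_seed(config$seed, 17L, i))
    }, error = function(e) {
      stop(sprintf("ensemble member %d failed: %s", i, conditionMessage(e)),
           call. = FALSE)
    })
    members[[i]] <- res
  }
  structure(list(transform = transform, subspaces = subspaces,
                 members = members,
                 weights = rep(1 / config$n_subspaces, config$n_subspaces),
                 classifier = config$classifier, config = config),
            class = "ensemble_model")
}

identity_transform <- function(train, standardize = TRUE) {
  d <- ncol(train$features)
  center <- scale <- NULL
  if (isTRUE(standardize)) {
    center <- colMeans(train$features)
    scale <- apply(train$features, 2L, stats::sd)
    scale[!is.finite(scale) | scale <= 0] <- 1
  }
  linear_transform(diag(1, d, d), center = center, scale = scale)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d members (%s), transform = %s\n",
              length(x$members), x$classifier$name, x$config$transform))
  cat(sprintf("  weights: %s\n",
              paste(sprintf("%.3f", x$weights), collapse = " ")))
  invisible(x)
}

#' Per-member scores on a dataset
#'
#' Transforms and projects the data once, then scores it through every
#' member. Column `j` equals member `j`'s score vector.
#'
#' @param model An [train_ensemble()] model.
#' @param data A [labeled_dataset()] with the training feature dimension.
#' @return `n x N` numeric score matrix.
#' @export
member_scores <- function(model, data) {
  z <- apply_transform(model$transform, data)
  cols <- lapply(seq_along(model$members), function(j) {
    model$classifier$score(model$members[[j]],
                           z$features[, model$subspaces[[j]], drop = FALSE])
  })
  do.call(cbind, cols)
}

#' Weighted-vote fusion of member scores
#'
#' The ensemble score is the weight-vector dot product with the member score
#' columns. Scores are continuous decision values, not hard labels, so the
#' combined score still ranks samples (as AUC evaluation requires); the hard
#' prediction thresholds it at 0.
#'
#' @param scores `n x N` member score matrix.
#' @param weights Length-`N` nonnegative weights summing to 1 (tolerance
#'   1e-9).
#' @return Length-`n` combined score vector.
#' @export
weighted_vote <- function(scores, weights) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(weights)) {
    imb_stop("imbfuse_dimension_error",
             "`weights` must have one entry per score column")
  }
  if (any(weights < -1e-9) || abs(sum(weights) - 1) > 1e-9) {
    imb_stop("imbfuse_parameter_error",
             "`weights` must be nonnegative and sum to 1")
  }
  as.numeric(scores %*% weights)
}

#' Predict with a fitted ensemble
#'
#' @param object An `ensemble_model`.
#' @param data A [labeled_dataset()].
#' @param type `"score"` for the combined continuous score, `"label"` for
#'   the hard 0/1 prediction (score thresholded at 0).
#' @param ... Unused.
#' @return Numeric score vector or integer label vector.
#' @export
predict.ensemble_model <- function(object, data, type = c("score", "label"),
                                   ...) {
  type <- match.arg(type)
  s <- weighted_vote(member_scores(object, data), object$weights)
  if (type == "score") s else as.integer(s > 0)
}
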