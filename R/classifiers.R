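# Base-classifier contract. A base classifier is a list with two closures:
#   fit(features, labels, seed)  -> fitted member object
#   score(member, features)      -> finite numeric vector, larger = more
#                                   minority-like (class 1)
# Any scorer honoring the contract can be plugged into the ensemble (e.g.
# a random forest for external baselines); the default is the linear
# max-margin classifier the protocol prescribes.

#' Linear max-margin base classifier
#'
#' A soft-margin linear support-vector classifier (cost parameter `cost`,
#' no internal rescaling — the pipeline standardizes upstream). The score is
#' the signed distance to the separating hyperplane, oriented so that larger
#' values favor the minority class (label 1).
#'
#' @param cost Regularization constant (default 1).
#' @return A `base_classifier` contract object with `fit` and `score`
#'   closures and a `name`.
#' @export
linear_svm_classifier <- function(cost = 1) {
  fit <- function(features, labels, seed = NULL) {
    yf <- factor(labels, levels = c(0L, 1L))
    e1071::svm(features, yf, kernel = "linear", cost = cost,
               scale = FALSE, probability = FALSE)
  }
  score <- function(member, features) {
    pred <- stats::predict(member, features, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    s <- as.numeric(dv[, 1L])
    # libsvm's decision column "A/B" is positive when favoring A
    if (!startsWith(colnames(dv)[1L], "1")) s <- -s
    s
  }
  structure(list(fit = fit, score = score, name = "linear_svm"),
            class = "base_classifier")
}

#' Wrap fit/score closures as a base classifier
#'
#' Escape hatch for plugging arbitrary scorers (including stochastic ones,
#' which must consume the `seed` argument of `fit`) into the ensemble.
#'
#' @param fit Function `(features, labels, seed)` returning a fitted object.
#' @param score Function `(member, features)` returning finite scores,
#'   larger = more minority-like.
#' @param name Short identifier used in logs.
#' @return A `base_classifier` contract object.
#' @export
base_classifier <- function(fit, score, name = "custom") {
  stopifnot(is.function(fit), is.function(score))
  structure(list(fit = fit, score = score, name = name),
            class = "base_classifier")
}
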