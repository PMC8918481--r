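# AUC computation and the repeated stratified cross-validation protocol:
# 5 runs x 5-fold CV by default, mean +/- std AUC, plus the subspace-count
# sweep experiment.

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann–Whitney U statistic with midrank
#' tie handling: the probability that a random minority (label 1) sample
#' outscores a random majority sample, ties counting one half.
#'
#' @param scores Length-`n` finite scores, larger = more minority-like.
#' @param labels Length-`n` binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    imb_stop("imbfuse_dimension_error",
             "`scores` and `labels` must have equal length")
  }
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    imb_stop("imbfuse_single_class_error",
             "AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # average ranks = midranks for ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Repeated stratified cross-validation of the pipeline
#'
#' For each of `runs` repetitions a fresh stratified `K`-fold split is drawn
#' (fold seed derived from the master seed and the run index). Per fold the
#' full pipeline — transform, subspaces, SMOTE, members, GA weights — is fit
#' on the training partition only, the held-out fold is scored, and its AUC
#' recorded. Folds whose test partition contains a single class are recorded
#' as `NA` and excluded from the aggregates with a warning.
#'
#' @param dataset A [labeled_dataset()]; each class needs `>= K` samples.
#' @param config An [ensemble_config()]; its `seed` is the master seed.
#' @param runs Number of repetitions (default 5).
#' @param K Fold count (default 5).
#' @return Object of class `cv_result`: list with `auc` (`runs x K` matrix),
#'   `mean_auc`, `std_auc` (population std over all run-folds),
#'   `per_run_mean`, `per_run_std`, and `config`.
#' @export
repeated_cv_evaluate <- function(dataset, config = ensemble_config(),
                                 runs = 5L, K = 5L) {
  runs <- as.integer(runs); K <- as.integer(K)
  auc <- matrix(NA_real_, nrow = runs, ncol = K,
                dimnames = list(paste0("run", seq_len(runs)),
                                paste0("fold", seq_len(K))))
  for (run in seq_len(runs)) {
    folds <- stratified_folds(dataset, K,
                              seed = derive_seed(config$seed, 29L, run))
    for (k in seq_len(K)) {
      test_idx <- which(folds$fold_index == k)
      test <- dataset_subset(dataset, test_idx)
      if (length(unique(test$labels)) < 2L) {
        warning(sprintf("run %d fold %d: single-class test partition, skipped",
                        run, k), call. = FALSE)
        next
      }
      fold_cfg <- config
      fold_cfg$seed <- derive_seed(config$seed, 31L, run, k)
      model <- fit_pipeline(dataset_subset(dataset, -test_idx), fold_cfg)
      auc[run, k] <- auc_score(predict(model, test), test$labels)
    }
  }
  vals <- auc[is.finite(auc)]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(auc = auc,
                 mean_auc = mean(vals),
                 std_auc = pop_sd(vals),
                 per_run_mean = rowMeans(auc, na.rm = TRUE),
                 per_run_std = apply(auc, 1L, function(x) {
                   x <- x[is.finite(x)]; pop_sd(x)
                 }),
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d runs x %d folds\n", nrow(x$auc), ncol(x$auc)))
  cat(sprintf("  AUC = %.4f +/- %.4f (over all run-folds)\n",
              x$mean_auc, x$std_auc))
  invisible(x)
}

#' Sweep the number of subspaces
#'
#' Repeats the full cross-validation protocol once per candidate ensemble
#' size with everything else fixed, to expose the diversity/redundancy
#' trade-off of the subspace count.
#'
#' @param dataset A [labeled_dataset()].
#' @param config An [ensemble_config()]; `n_subspaces` is overridden per row.
#' @param N_values Integer vector of ensemble sizes to try.
#' @param runs,K Protocol repetitions and fold count.
#' @return Data frame with columns `n_subspaces`, `mean_auc`, `std_auc`,
#'   rows in input order.
#' @export
subspace_sweep <- function(dataset, config = ensemble_config(),
                           N_values = c(5L, 10L, 15L, 20L),
                           runs = 5L, K = 5L) {
  rows <- lapply(N_values, function(nv) {
    cfg <- config
    cfg$n_subspaces <- as.integer(nv)
    res <- repeated_cv_evaluate(dataset, cfg, runs = runs, K = K)
    data.frame(n_subspaces = as.integer(nv), mean_auc = res$mean_auc,
               std_auc = res$std_auc)
  })
  do.call(rbind, rows)
}

#' Plot a subspace sweep
#'
#' Mean AUC against ensemble size with a +/- one-std ribbon. Requires
#' ggplot2.
#'
#' @param sweep A [subspace_sweep()] result.
#' @return A ggplot object.
#' @export
plot_subspace_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    imb_stop("imbfuse_parameter_error", "ggplot2 is required for plotting")
  }
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_subspaces,
                                      y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$std_auc,
                                      ymax = .data$mean_auc + .data$std_auc),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of subspaces", y = "mean AUC")
}
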