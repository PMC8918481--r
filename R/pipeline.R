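#' Fit the full adaptive-fusion pipeline
#'
#' End-to-end training on one partition: holds out a stratified
#' `ga_fraction` validation slice, trains the transform + subspace +
#' SMOTE + base-classifier ensemble on the remainder (so metric learning
#' and member training never see the validation slice), scores the slice
#' through every member, and runs the genetic algorithm to set the voting
#' weights. With `config$use_ga = FALSE` the ensemble is trained on the
#' whole partition with uniform weights.
#'
#' @param train A [labeled_dataset()] with both classes present.
#' @param config An [ensemble_config()].
#' @return An `ensemble_model` with GA-optimized `weights`; the GA trace is
#'   attached as attribute `ga_state`.
#' @export
fit_pipeline <- function(train, config = ensemble_config()) {
  if (!config$use_ga) {
    return(train_ensemble(train, config))
  }
  split <- stratified_split(train, config$ga_fraction,
                            seed = derive_seed(config$seed, 19L))
  fit_part <- dataset_subset(train, split$fit)
  val_part <- dataset_subset(train, split$holdout)
  model <- train_ensemble(fit_part, config)
  scores <- member_scores(model, val_part)
  ga_cfg <- config$ga
  ga_cfg$seed <- derive_seed(config$seed, 23L)
  res <- evolve(scores, val_part$labels, ga_cfg)
  model$weights <- res$weights
  attr(model, "ga_state") <- res$state
  model
}
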