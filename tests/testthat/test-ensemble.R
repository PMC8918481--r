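test_that("subspace sizes follow the floor rule", {
  s18 <- sample_subspaces(18, 0.7, 15, seed = 1)
  expect_true(all(lengths(s18) == 12L))

  s784 <- sample_subspaces(784, 0.1, 3, seed = 1)
  expect_true(all(lengths(s784) == 78L))

  full <- sample_subspaces(9, 1.0, 4, seed = 2)
  for (sub in full) expect_identical(sub, 1:9)

  expect_error(sample_subspaces(10, 0.5, 0, seed = 1),
               class = "imbfuse_parameter_error")
  expect_error(sample_subspaces(10, 1.2, 3, seed = 1),
               class = "imbfuse_parameter_error")
})

test_that("subspace draws are valid, seeded and independent", {
  for (seed in 1:5) {
    subs <- sample_subspaces(11, 0.6, 10, seed = seed)
    for (sub in subs) {
      expect_identical(anyDuplicated(sub), 0L)
      expect_true(all(diff(sub) > 0))
      expect_true(all(sub >= 1 & sub <= 11))
    }
  }
  expect_identical(sample_subspaces(11, 0.6, 10, seed = 3),
                   sample_subspaces(11, 0.6, 10, seed = 3))
  expect_false(identical(sample_subspaces(11, 0.6, 10, seed = 3),
                         sample_subspaces(11, 0.6, 10, seed = 4)))
})

test_that("weighted vote is the simplex-weighted column sum", {
  set.seed(12)
  s <- matrix(rnorm(40), 10, 4)
  expect_equal(weighted_vote(s, c(1, 0, 0, 0)), s[, 1])
  expect_equal(weighted_vote(s, rep(0.25, 4)), rowMeans(s))

  w <- runif(4); w <- w / sum(w)
  by_hand <- numeric(10)
  for (i in 1:10) for (j in 1:4) by_hand[i] <- by_hand[i] + w[j] * s[i, j]
  expect_equal(weighted_vote(s, w), by_hand, tolerance = 1e-12)

  # linearity in the weights
  w2 <- runif(4); w2 <- w2 / sum(w2)
  a <- 0.3
  expect_equal(weighted_vote(s, a * w + (1 - a) * w2),
               a * weighted_vote(s, w) + (1 - a) * weighted_vote(s, w2),
               tolerance = 1e-12)

  expect_error(weighted_vote(s, c(0.5, 0.5, 0.5, 0.5)),
               class = "imbfuse_parameter_error")
  expect_error(weighted_vote(s, c(0.5, 0.5)),
               class = "imbfuse_dimension_error")
})

test_that("trained ensembles have the declared structure and determinism", {
  ds <- generate_synthetic(synthetic_spec(80, 16, 2, 2, 3, seed = 21))
  cfg <- ensemble_config(n_subspaces = 15, seed = 5, use_ga = FALSE,
                         imlmnn = imlmnn_config(max_iters = 20))
  model <- train_ensemble(ds, cfg)
  expect_length(model$members, 15L)
  expect_length(model$subspaces, 15L)
  expect_equal(model$weights, rep(1 / 15, 15))

  probe <- generate_synthetic(synthetic_spec(20, 5, 2, 2, 3, seed = 99))
  s1 <- member_scores(model, probe)
  model2 <- train_ensemble(ds, cfg)
  expect_identical(member_scores(model2, probe), s1)
  expect_identical(dim(s1), c(25L, 15L))
})

test_that("member scores are the per-member projections they claim", {
  ds <- generate_synthetic(synthetic_spec(60, 12, 2, 2, 3, seed = 31))
  cfg <- ensemble_config(n_subspaces = 4, seed = 2, use_ga = FALSE,
                         imlmnn = imlmnn_config(max_iters = 10))
  model <- train_ensemble(ds, cfg)
  probe <- generate_synthetic(synthetic_spec(15, 4, 2, 2, 3, seed = 7))
  s <- member_scores(model, probe)
  z <- apply_transform(model$transform, probe)
  for (j in 1:4) {
    direct <- model$classifier$score(
      model$members[[j]], z$features[, model$subspaces[[j]], drop = FALSE])
    expect_equal(s[, j], direct)
  }
  # permuting rows permutes scores identically
  perm <- sample(nrow(probe$features))
  s_perm <- member_scores(model, dataset_subset(probe, perm))
  expect_equal(s_perm, s[perm, ])
})

test_that("a degenerate ensemble equals a plain SMOTE + classifier pipeline", {
  ds <- generate_synthetic(synthetic_spec(50, 10, 2, 1, 3, seed = 41))
  cfg <- ensemble_config(transform = "none", n_subspaces = 1,
                         feature_ratio = 1.0, seed = 9, use_ga = FALSE,
                         imlmnn = imlmnn_config(standardize = FALSE))
  model <- train_ensemble(ds, cfg)
  probe <- generate_synthetic(synthetic_spec(12, 3, 2, 1, 3, seed = 8))
  ens_scores <- predict(model, probe)

  bal <- smote_balance(ds, smote_params(5, derive_seed(9L, 13L, 1L)))
  clf <- linear_svm_classifier()
  member <- clf$fit(bal$features, bal$labels)
  expect_equal(ens_scores, clf$score(member, probe$features))
})

test_that("base classifier scores are oriented towards the minority class", {
  ds <- generate_synthetic(synthetic_spec(60, 20, 2, 0, 6, seed = 3))
  clf <- linear_svm_classifier()
  m <- clf$fit(ds$features, ds$labels)
  s <- clf$score(m, ds$features)
  expect_gt(mean(s[ds$labels == 1L]), mean(s[ds$labels == 0L]))
  expect_true(all(is.finite(s)))
})

test_that("the GA-fitted pipeline returns simplex weights and predicts", {
  ds <- generate_synthetic(synthetic_spec(100, 25, 2, 2, 3, seed = 51))
  cfg <- ensemble_config(n_subspaces = 5, seed = 3,
                         imlmnn = imlmnn_config(max_iters = 15),
                         ga = ga_config(max_generations = 10))
  model <- fit_pipeline(ds, cfg)
  expect_equal(sum(model$weights), 1, tolerance = 1e-12)
  expect_true(all(model$weights >= 0))
  expect_s3_class(attr(model, "ga_state"), "ga_state")

  labels <- predict(model, ds, type = "label")
  expect_true(all(labels %in% c(0L, 1L)))
})
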