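test_that("class centers are class means", {
  ds <- labeled_dataset(rbind(c(0, 0), c(2, 2), c(3, 1), c(5, 9)),
                        c(0L, 0L, 1L, 1L))
  expect_equal(unname(class_center(ds, 0)), c(1, 1))
  expect_equal(unname(class_center(ds, 1)), c(4, 5))

  big <- random_instance(25, 5, seed = 41)
  idx <- which(big$labels == 0L)
  by_hand <- vapply(seq_len(5), function(j) {
    s <- 0
    for (i in idx) s <- s + big$features[i, j]
    s / length(idx)
  }, numeric(1))
  expect_equal(unname(class_center(big, 0)), by_hand, tolerance = 1e-12)
})

test_that("sample density matches definitions and clamps zero distances", {
  ds <- labeled_dataset(matrix(c(0, 1, 2), ncol = 1), c(0L, 0L, 1L))
  dens <- sample_density(2, ds, density_params(k = 1, h = 1))
  expect_equal(dens$delta_n, 1)
  expect_equal(dens$delta_p, 1)
  expect_equal(dens$delta, 2)

  # duplicate of the anchor: mean distance 0 is clamped to epsilon
  dup <- labeled_dataset(matrix(c(0, 0, 5, 9), ncol = 1),
                         c(0L, 0L, 1L, 1L))
  dd <- sample_density(1, dup, density_params(k = 1, h = 1, epsilon = 1e-12))
  expect_equal(dd$delta_n, 1e12)
  expect_true(is.finite(dd$delta))

  expect_error(sample_density(1, ds, density_params(k = 5, h = 1)),
               class = "imbfuse_insufficient_error")
})

test_that("sample weights agree with a straight-line oracle", {
  ds <- random_instance(40, 3, seed = 7)
  w <- sample_weights(ds, density_params(k = 3, h = 3))
  expect_equal(w, oracle_weights(ds$features, ds$labels, 3, 3),
               tolerance = 1e-12)
  expect_true(all(w > 0 & is.finite(w)))
})

test_that("mirrored fixture yields the exact class-size weight ratio", {
  ds <- mirrored_fixture()
  w <- sample_weights(ds, density_params(k = 1, h = 1))
  # anchors 1 (majority) and 5 (minority) share density and center distance
  expect_identical(w[5] / w[1], 2)
})

test_that("weights stay finite for a sample at its own class center", {
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(0, 0),   # maj, mean 0
             c(6, 0), c(8, 0), c(7, 1))                        # minority
  ds <- labeled_dataset(x, c(rep(0L, 5), rep(1L, 3)))
  w <- sample_weights(ds, density_params(k = 2, h = 2, epsilon = 1e-12))
  expect_true(all(is.finite(w)))
  expect_gt(w[5], 0)  # row 5 sits exactly at the majority mean
})

test_that("triplet construction counts and matches a sort oracle", {
  ds6 <- random_instance(6, 2, seed = 3, min_frac = 0.5)
  tr <- build_triplets(ds6, 1)
  expect_identical(nrow(tr$pull), 6L)
  expect_identical(nrow(tr$push), 18L)

  # k_targets = class size - 1 covers all same-class ordered pairs
  tr2 <- build_triplets(ds6, 2)
  expect_identical(nrow(tr2$pull), 12L)
  pairs <- paste(tr2$pull[, 1], tr2$pull[, 2])
  all_same <- unlist(lapply(1:6, function(i) {
    paste(i, setdiff(which(ds6$labels == ds6$labels[i]), i))
  }))
  expect_setequal(pairs, all_same)

  ds <- random_instance(24, 4, seed = 13)
  tr3 <- build_triplets(ds, 3)
  for (i in seq_len(24)) {
    mine <- sort(tr3$pull[tr3$pull[, 1] == i, 2])
    expect_identical(mine, sort(oracle_targets(ds$features, ds$labels, i, 3)))
  }
  # push triplets: every pull pair crossed with every opposite-class sample
  expect_identical(nrow(tr3$push),
                   sum(3L * table(ds$labels)[as.character(1 - ds$labels)]))

  expect_error(build_triplets(ds6, 3), class = "imbfuse_insufficient_error")
})

test_that("losses match the brute-force triple loop on random instances", {
  for (seed in 1:10) {
    ds <- random_instance(sample(10:25, 1), sample(2:4, 1), seed = seed)
    k <- 2L
    w <- sample_weights(ds, density_params(k = 2, h = 2))
    tr <- build_triplets(ds, k)
    L <- matrix(rnorm(3 * ncol(ds$features)), 3)
    expect_equal(imlmnn_loss(L, ds, w, tr, margin = 1),
                 oracle_loss(L, ds$features, ds$labels, w, k, 1),
                 tolerance = 1e-10)
    ones <- rep(1, nrow(ds$features))
    expect_equal(lmnn_loss(L, ds, tr, margin = 1),
                 oracle_loss(L, ds$features, ds$labels, ones, k, 1),
                 tolerance = 1e-10)
  }
})

test_that("loss degenerates correctly at the zero map and inactive hinges", {
  ds <- random_instance(14, 3, seed = 5)
  w <- sample_weights(ds, density_params(k = 2, h = 2))
  tr <- build_triplets(ds, 2)
  zero <- matrix(0, 3, 3)
  expect_equal(imlmnn_loss(zero, ds, w, tr, margin = 1),
               sum(w[tr$push[, 1]]))
  expect_equal(lmnn_loss(zero, ds, tr, margin = 1), nrow(tr$push))

  # well-separated classes: every hinge inactive under the identity
  far <- labeled_dataset(rbind(c(0, 0), c(1, 0), c(0, 1),
                               c(100, 0), c(101, 0), c(100, 1)),
                         c(0L, 0L, 0L, 1L, 1L, 1L))
  wf <- rep(1, 6)
  trf <- build_triplets(far, 1)
  pull_only <- sum(vapply(seq_len(nrow(trf$pull)), function(p) {
    sum((far$features[trf$pull[p, 1], ] - far$features[trf$pull[p, 2], ])^2)
  }, numeric(1)))
  expect_equal(imlmnn_loss(diag(2), far, wf, trf, margin = 1), pull_only)
})

test_that("unit weights reduce the weighted loss to the classic loss", {
  for (seed in 1:5) {
    ds <- random_instance(16, 3, seed = 100 + seed)
    tr <- build_triplets(ds, 2)
    L <- matrix(rnorm(6), 2, 3)
    expect_equal(imlmnn_loss(L, ds, rep(1, 16), tr, 1),
                 lmnn_loss(L, ds, tr, 1), tolerance = 1e-12)
  }
})

test_that("analytic gradient matches central differences away from kinks", {
  ds <- random_instance(15, 3, seed = 21)
  w <- sample_weights(ds, density_params(k = 2, h = 2))
  tr <- build_triplets(ds, 2)
  set.seed(77)
  checked <- 0
  while (checked < 5) {
    L <- matrix(rnorm(9, sd = 0.5), 3, 3)
    z <- ds$features %*% t(L)
    d2t <- rowSums((z[tr$push[, 1], ] - z[tr$push[, 2], ])^2)
    d2i <- rowSums((z[tr$push[, 1], ] - z[tr$push[, 3], ])^2)
    if (min(abs(1 + d2t - d2i)) < 1e-4) next  # resample away from kinks
    g <- imlmnn_gradient(L, ds, w, tr, 1)
    eps <- 1e-6
    num <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      Lp <- L; Lp[a, b] <- Lp[a, b] + eps
      Lm <- L; Lm[a, b] <- Lm[a, b] - eps
      num[a, b] <- (imlmnn_loss(Lp, ds, w, tr, 1) -
                      imlmnn_loss(Lm, ds, w, tr, 1)) / (2 * eps)
    }
    expect_lt(max(abs(g - num)) / max(abs(g)), 1e-5)
    checked <- checked + 1
  }
})

test_that("gradient is zero at the zero map and linear in the weights", {
  ds <- random_instance(12, 2, seed = 31)
  w <- sample_weights(ds, density_params(k = 2, h = 2))
  tr <- build_triplets(ds, 2)
  expect_equal(imlmnn_gradient(matrix(0, 2, 2), ds, w, tr, 1),
               matrix(0, 2, 2))
  L <- matrix(rnorm(4), 2, 2)
  expect_equal(imlmnn_gradient(L, ds, 2 * w, tr, 1),
               2 * imlmnn_gradient(L, ds, w, tr, 1), tolerance = 1e-12)
})

test_that("fitting descends monotonically and is deterministic", {
  ds <- generate_synthetic(synthetic_spec(60, 15, 2, 4, 4, seed = 17))

  frozen <- fit_imlmnn(ds, imlmnn_config(max_iters = 0))
  expect_equal(frozen$L, diag(1, 6, 6))

  cfg <- imlmnn_config(max_iters = 60)
  ft <- fit_imlmnn(ds, cfg)
  h <- attr(ft, "loss_history")
  expect_true(all(diff(h) <= 0))
  expect_lt(h[length(h)], h[1])
  expect_identical(fit_imlmnn(ds, cfg)$L, ft$L)

  # truncated output dimension
  low <- fit_imlmnn(ds, imlmnn_config(max_iters = 5, output_dim = 3))
  expect_identical(dim(low$L), c(3L, 6L))
})

test_that("the learned map improves relative class separation", {
  improved <- 0
  for (seed in 1:5) {
    ds <- generate_synthetic(synthetic_spec(100, 20, 2, 4, 2, seed = seed))
    ft <- fit_imlmnn(ds, imlmnn_config(max_iters = 150))
    base <- linear_transform(diag(1, ncol(ds$features)), ft$center, ft$scale)
    r0 <- mean_separation_ratio(apply_transform(base, ds))
    r1 <- mean_separation_ratio(apply_transform(ft, ds))
    improved <- improved + (r1 > r0)
  }
  expect_gte(improved, 4)
})

test_that("apply_transform is the row-wise linear map it claims to be", {
  ds <- random_instance(10, 4, seed = 9)
  id <- linear_transform(diag(4))
  expect_equal(apply_transform(id, ds)$features, unname(ds$features),
               ignore_attr = TRUE)

  L <- matrix(rnorm(12), 3, 4)
  tr <- linear_transform(L)
  z <- apply_transform(tr, ds)
  for (i in 1:10) {
    expect_equal(unname(z$features[i, ]), as.numeric(L %*% ds$features[i, ]),
                 tolerance = 1e-12)
  }

  # scaling L scales all pairwise distances
  z2 <- apply_transform(linear_transform(3 * L), ds)
  expect_equal(as.numeric(dist(z2$features)), 3 * as.numeric(dist(z$features)),
               tolerance = 1e-12)

  expect_error(apply_transform(tr, random_instance(10, 5, seed = 1)),
               class = "imbfuse_dimension_error")
})
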