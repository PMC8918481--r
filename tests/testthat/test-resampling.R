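test_that("interpolation follows the segment contract", {
  expect_equal(smote_synthesize(c(0, 0), c(2, 2), 0.5), c(1, 1))
  expect_equal(smote_synthesize(c(1, 5), c(3, -2), 0), c(1, 5))
  expect_equal(smote_synthesize(c(1, 5), c(3, -2), 1), c(3, -2))

  set.seed(2)
  for (rep in 1:20) {
    a <- rnorm(4); b <- rnorm(4); r <- runif(1)
    s <- smote_synthesize(a, b, r)
    expect_true(all(s >= pmin(a, b) - 1e-12 & s <= pmax(a, b) + 1e-12))
  }

  expect_error(smote_synthesize(1:2, 1:3, 0.5),
               class = "imbfuse_dimension_error")
  expect_error(smote_synthesize(1:2, 2:3, 1.5),
               class = "imbfuse_parameter_error")
})

test_that("balancing fills the quota and preserves originals verbatim", {
  ds <- generate_synthetic(synthetic_spec(50, 10, 2, 1, 3, seed = 4))
  bal <- smote_balance(ds, smote_params(k_neighbors = 3, seed = 6))
  expect_identical(nrow(bal$features), 100L)
  expect_identical(sum(bal$labels == 1L), 50L)
  expect_identical(bal$features[1:60, ], ds$features)
  expect_identical(bal$labels[1:60], ds$labels)

  prov <- attr(bal, "provenance")
  expect_identical(nrow(prov), 40L)
  # every minority sample contributes before any repeats
  expect_identical(sort(unique(prov$seed_index[1:10])),
                   which(ds$labels == 1L))
})

test_that("already balanced input is returned unchanged", {
  ds <- generate_synthetic(synthetic_spec(10, 10, 2, 0, 3, seed = 2))
  bal <- smote_balance(ds, smote_params(seed = 1))
  expect_identical(bal$features, ds$features)
  expect_identical(nrow(attr(bal, "provenance")), 0L)
})

test_that("synthetic rows lie on their recorded seed-neighbor segments", {
  ds <- generate_synthetic(synthetic_spec(40, 8, 3, 0, 2, seed = 9))
  bal <- smote_balance(ds, smote_params(k_neighbors = 3, seed = 11))
  prov <- attr(bal, "provenance")
  for (t in seq_len(nrow(prov))) {
    rebuilt <- smote_synthesize(ds$features[prov$seed_index[t], ],
                                ds$features[prov$neighbor_index[t], ],
                                prov$r[t])
    expect_equal(unname(bal$features[prov$row[t], ]), unname(rebuilt),
                 tolerance = 1e-12)
  }
  # neighbor really is among the seed's k nearest minority rows
  minority <- which(ds$labels == 1L)
  for (t in seq_len(nrow(prov))) {
    seed_row <- prov$seed_index[t]
    d <- vapply(minority, function(j) {
      slow_dist(ds$features[seed_row, ], ds$features[j, ])
    }, numeric(1))
    nearest3 <- minority[order(d, minority)][2:4]  # skip the seed itself
    expect_true(prov$neighbor_index[t] %in% nearest3)
  }
})

test_that("balancing is deterministic per seed and varies across seeds", {
  ds <- generate_synthetic(synthetic_spec(30, 6, 2, 2, 2, seed = 3))
  a <- smote_balance(ds, smote_params(seed = 5))
  b <- smote_balance(ds, smote_params(seed = 5))
  expect_identical(a$features, b$features)
  c <- smote_balance(ds, smote_params(seed = 6))
  expect_false(identical(a$features, c$features))
})

test_that("edge cases: capped neighbors and singleton minority", {
  tiny <- labeled_dataset(rbind(matrix(rnorm(20), 10, 2),
                                c(0, 0), c(1, 1), c(0, 1)),
                          c(rep(0L, 10), 1L, 1L, 1L))
  expect_warning(smote_balance(tiny, smote_params(k_neighbors = 5, seed = 1)),
                 "capped")

  singleton <- labeled_dataset(rbind(matrix(rnorm(10), 5, 2), c(0, 0)),
                               c(rep(0L, 5), 1L))
  expect_error(smote_balance(singleton, smote_params(seed = 1)),
               class = "imbfuse_insufficient_error")
})

test_that("provenance log writes as delimited text", {
  ds <- generate_synthetic(synthetic_spec(20, 5, 2, 0, 3, seed = 1))
  bal <- smote_balance(ds, smote_params(k_neighbors = 3, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_provenance(bal, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 15L)
  expect_named(back, c("row", "seed_index", "neighbor_index", "r"))
})
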