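# SMOTE oversampling of the minority class. Synthetic points are convex
# interpolations x_i + (x_n - x_i) * r between a minority seed x_i and one
# of its k nearest minority neighbors x_n, with r uniform on [0, 1]. The
# pipeline applies it inside each feature subspace, after the learned
# transform and the column projection.

#' SMOTE parameters
#'
#' @param k_neighbors Candidate same-class neighbors per seed sample
#'   (classical default 5); silently capped at minority size − 1 with a
#'   warning when the minority class is smaller.
#' @param seed Integer seed driving seed-sample order, neighbor choice and
#'   the interpolation draw.
#' @return An object of class `smote_params`.
#' @export
smote_params <- function(k_neighbors = 5L, seed = 1L) {
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) {
    imb_stop("imbfuse_parameter_error", "`k_neighbors` must be >= 1")
  }
  structure(list(k_neighbors = k_neighbors, seed = as.integer(seed)),
            class = "smote_params")
}

#' Interpolate one synthetic sample
#'
#' @param x_i Seed sample (numeric vector).
#' @param x_n Neighbor sample of the same length.
#' @param r Interpolation coefficient in `[0, 1]`.
#' @return `x_i + (x_n - x_i) * r`.
#' @export
smote_synthesize <- function(x_i, x_n, r) {
  if (length(x_i) != length(x_n)) {
    imb_stop("imbfuse_dimension_error",
             "`x_i` and `x_n` must have equal length")
  }
  if (!is.finite(r) || r < 0 || r > 1) {
    imb_stop("imbfuse_parameter_error", "`r` must lie in [0, 1]")
  }
  x_i + (x_n - x_i) * r
}

#' Balance a dataset by SMOTE oversampling
#'
#' Appends `n_majority - n_minority` synthetic minority rows. Seeds are
#' drawn by cycling through the minority samples in a shuffled order (every
#' minority sample contributes before any repeats); for each seed one of its
#' `k_neighbors` nearest minority neighbors (Euclidean, in the dataset's
#' current coordinates; ties by lower index) is picked uniformly and the
#' interpolation coefficient is uniform on `[0, 1]`. Original rows are
#' preserved verbatim and come first. Deterministic for a fixed seed.
#'
#' @param dataset A [labeled_dataset()] with at least 2 minority samples.
#' @param params A [smote_params()].
#' @return A class-balanced [labeled_dataset()]; attribute `provenance` is a
#'   data frame with one row per synthetic sample (`row`, `seed_index`,
#'   `neighbor_index`, `r`) recording how it was built.
#' @export
smote_balance <- function(dataset, params = smote_params()) {
  labels <- dataset$labels
  min_idx <- which(labels == 1L)
  n_min <- length(min_idx)
  n_maj <- sum(labels == 0L)
  if (n_min < 2L) {
    imb_stop("imbfuse_insufficient_error",
             "SMOTE needs at least 2 minority samples")
  }
  quota <- n_maj - n_min
  if (quota <= 0L) {
    attr(dataset, "provenance") <- data.frame(
      row = integer(0), seed_index = integer(0),
      neighbor_index = integer(0), r = numeric(0))
    return(dataset)
  }
  k <- params$k_neighbors
  if (k > n_min - 1L) {
    k <- n_min - 1L
    warning(sprintf("k_neighbors capped at minority size - 1 = %d", k),
            call. = FALSE)
  }
  xmin <- dataset$features[min_idx, , drop = FALSE]
  d2 <- pairwise_sqdist(xmin)
  diag(d2) <- Inf
  # k nearest minority neighbors of each minority sample, ties by lower index
  nn <- t(apply(d2, 1L, function(row) {
    order(row, seq_along(row), method = "radix")[seq_len(k)]
  }))
  if (k == 1L) nn <- matrix(nn, ncol = 1L)

  with_seed(params$seed, {
    cycle <- rep_len(sample.int(n_min), quota)
    synth <- matrix(0, nrow = quota, ncol = ncol(dataset$features))
    prov <- data.frame(row = nrow(dataset$features) + seq_len(quota),
                       seed_index = min_idx[cycle],
                       neighbor_index = 0L, r = 0)
    for (t in seq_len(quota)) {
      s <- cycle[t]
      nb <- nn[s, sample.int(k, 1L)]
      r <- stats::runif(1L)
      synth[t, ] <- smote_synthesize(xmin[s, ], xmin[nb, ], r)
      prov$neighbor_index[t] <- min_idx[nb]
      prov$r[t] <- r
    }
    out <- labeled_dataset(rbind(dataset$features, synth),
                           c(labels, rep(1L, quota)),
                           feature_names = dataset$feature_names)
    attr(out, "provenance") <- prov
    out
  })
}

#' Write a SMOTE provenance log as delimited text
#'
#' @param dataset A dataset returned by [smote_balance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(dataset, path) {
  prov <- attr(dataset, "provenance")
  if (is.null(prov)) {
    imb_stop("imbfuse_format_error", "dataset carries no provenance log")
  }
  utils::write.csv(prov, path, row.names = FALSE)
  invisible(path)
}
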