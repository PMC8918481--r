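# Imbalance-weighted large-margin nearest-neighbor (ImLMNN) metric learning.
#
# The learner finds a linear map L (r x d) minimizing
#
#   f(L) = sum_{(i,j)} w_i ||L(x_i - x_j)||^2
#        + sum_{(i,j)} sum_l w_i [ margin + ||L(x_i - x_j)||^2
#                                         - ||L(x_i - x_l)||^2 ]_+
#
# where (i,j) ranges over each anchor and its k nearest same-class "target
# neighbors" (fixed in the original space), l over every different-class
# "impostor", [z]_+ = max(z, 0), and w_i is an imbalance-aware anchor weight
#
#   w_i = delta_i / ( |N_c| * d(x_i, center_c) ),   c = class of x_i,
#
# with delta_i the sum of inverse mean distances to the k nearest majority
# and h nearest minority neighbors (boundary-density emphasis), |N_c| the
# anchor's class size (class-size normalization) and d(x_i, center_c) the
# distance to the anchor's own class mean (outlier down-weighting). Setting
# all w_i = 1 recovers the classic LMNN loss.

#' Neighborhood-density parameters for sample weighting
#'
#' @param k Number of majority-class neighbors in the density term.
#' @param h Number of minority-class neighbors in the density term.
#' @param epsilon Small positive guard: any mean neighbor distance or
#'   center distance below `epsilon` is clamped to `epsilon`, keeping every
#'   weight finite and strictly positive.
#' @return An object of class `density_params`.
#' @export
density_params <- function(k = 5L, h = 5L, epsilon = 1e-12) {
  k <- as.integer(k); h <- as.integer(h)
  if (k < 1L || h < 1L || !is.finite(epsilon) || epsilon <= 0) {
    imb_stop("imbfuse_parameter_error",
             "need k >= 1, h >= 1 and epsilon > 0")
  }
  structure(list(k = k, h = h, epsilon = epsilon),
            class = "density_params")
}

#' Configuration for the ImLMNN / LMNN fit
#'
#' @param k_targets Target-neighbor count per anchor (same-class pulls).
#' @param density A [density_params()] object for the sample weights.
#' @param margin Hinge margin of the push term (the literal unit margin).
#' @param max_iters Maximum gradient-descent iterations (`0` returns the
#'   initialization unchanged).
#' @param learning_rate Initial gradient step size, applied to standardized
#'   features.
#' @param min_rel_improvement Stop when the relative loss improvement of an
#'   accepted step falls below this.
#' @param output_dim Number of rows `r` of the learned map; `NULL` keeps the
#'   input dimension.
#' @param standardize Standardize features (zero mean, unit variance, fitted
#'   on the training data) before learning; the returned transform carries
#'   the standardization so it is replayed on new data.
#' @param seed Integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @return An object of class `imlmnn_config`.
#' @export
imlmnn_config <- function(k_targets = 3L, density = density_params(),
                          margin = 1, max_iters = 200L,
                          learning_rate = 1e-3,
                          min_rel_improvement = 1e-6,
                          output_dim = NULL, standardize = TRUE,
                          seed = 1L) {
  if (!is.finite(margin) || margin <= 0) {
    imb_stop("imbfuse_parameter_error", "`margin` must be positive")
  }
  if (max_iters < 0L) {
    imb_stop("imbfuse_parameter_error", "`max_iters` must be >= 0")
  }
  if (learning_rate <= 0) {
    imb_stop("imbfuse_parameter_error", "`learning_rate` must be positive")
  }
  structure(list(k_targets = as.integer(k_targets), density = density,
                 margin = margin, max_iters = as.integer(max_iters),
                 learning_rate = learning_rate,
                 min_rel_improvement = min_rel_improvement,
                 output_dim = output_dim, standardize = standardize,
                 seed = as.integer(seed)),
            class = "imlmnn_config")
}

#' Linear feature-space transform
#'
#' Wraps the learned `r x d` matrix `L` together with the standardization
#' fitted on the training data, so that `apply_transform()` replays the full
#' map `x -> L ((x - center) / scale)` on any dataset. Distances in the
#' learned space are `||L (x_i - x_j)||`.
#'
#' @param L Numeric `r x d` matrix with finite entries.
#' @param center,scale Optional length-`d` standardization vectors (`NULL`
#'   means no standardization).
#' @return An object of class `linear_transform`.
#' @export
linear_transform <- function(L, center = NULL, scale = NULL) {
  L <- as.matrix(L)
  storage.mode(L) <- "double"
  if (nrow(L) < 1L || !all(is.finite(L))) {
    imb_stop("imbfuse_format_error",
             "`L` must be a finite matrix with at least one row")
  }
  if (!is.null(center) && length(center) != ncol(L)) {
    imb_stop("imbfuse_dimension_error", "`center` must have length d")
  }
  if (!is.null(scale) && length(scale) != ncol(L)) {
    imb_stop("imbfuse_dimension_error", "`scale` must have length d")
  }
  structure(list(L = L, center = center, scale = scale),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat(sprintf("linear_transform: %d x %d map%s\n", nrow(x$L), ncol(x$L),
              if (is.null(x$center)) "" else " (with standardization)"))
  invisible(x)
}

as_transform_matrix <- function(L) {
  if (inherits(L, "linear_transform")) L$L else as.matrix(L)
}

standardize_features <- function(x, center, scale) {
  if (!is.null(center)) x <- sweep(x, 2L, center, "-")
  if (!is.null(scale)) x <- sweep(x, 2L, scale, "/")
  x
}

#' Mean of one class's feature rows
#'
#' The geometric center used in the outlier down-weighting term of the
#' sample weights.
#'
#' @param dataset A [labeled_dataset()].
#' @param class_label `0` or `1`.
#' @return Length-`d` numeric vector.
#' @export
class_center <- function(dataset, class_label) {
  idx <- which(dataset$labels == as.integer(class_label))
  if (length(idx) == 0L) {
    imb_stop("imbfuse_empty_class_error",
             sprintf("class %s is empty", class_label))
  }
  colMeans(dataset$features[idx, , drop = FALSE])
}

#' Neighborhood density of one sample
#'
#' `delta_n` is the inverse of the mean Euclidean distance from sample `i`
#' to its `k` nearest majority-class neighbors; `delta_p` likewise with the
#' `h` nearest minority-class neighbors; `delta = delta_n + delta_p`. The
#' sample itself is never its own neighbor. A mean distance below
#' `params$epsilon` is clamped to `epsilon`, so densities stay finite even
#' with duplicated points.
#'
#' @param i Sample index.
#' @param dataset A [labeled_dataset()].
#' @param params A [density_params()].
#' @return Named list with `delta_n`, `delta_p`, `delta`.
#' @export
sample_density <- function(i, dataset, params = density_params()) {
  d2 <- pairwise_sqdist(dataset$features[i, , drop = FALSE],
                        dataset$features)
  dens <- density_from_sqdist(sqrt(d2[1L, ]), i, dataset$labels, params)
  dens
}

density_from_sqdist <- function(dist_i, i, labels, params) {
  maj <- setdiff(which(labels == 0L), i)
  mnr <- setdiff(which(labels == 1L), i)
  if (length(maj) < params$k || length(mnr) < params$h) {
    imb_stop("imbfuse_insufficient_error",
             sprintf("need %d majority and %d minority neighbors excluding the anchor; have %d and %d",
                     params$k, params$h, length(maj), length(mnr)))
  }
  mean_k <- mean(sort(dist_i[maj], method = "radix")[seq_len(params$k)])
  mean_h <- mean(sort(dist_i[mnr], method = "radix")[seq_len(params$h)])
  delta_n <- 1 / max(mean_k, params$epsilon)
  delta_p <- 1 / max(mean_h, params$epsilon)
  list(delta_n = delta_n, delta_p = delta_p, delta = delta_n + delta_p)
}

#' Imbalance-aware anchor weights
#'
#' Computes `w_i = delta_i / (|N_c| * d(x_i, center_c))` for every sample,
#' where `c` is the sample's own class, `|N_c|` its size and `center_c` its
#' mean. Minority samples therefore carry weights larger by the class-size
#' ratio, boundary samples by their neighborhood density, and outliers are
#' damped by their distance to the class center.
#'
#' @param dataset A [labeled_dataset()] with both classes present.
#' @param params A [density_params()].
#' @return Length-`n` vector of strictly positive finite weights.
#' @export
sample_weights <- function(dataset, params = density_params()) {
  n <- nrow(dataset$features)
  dist_all <- sqrt(pairwise_sqdist(dataset$features))
  centers <- rbind(class_center(dataset, 0L), class_center(dataset, 1L))
  class_sizes <- c(sum(dataset$labels == 0L), sum(dataset$labels == 1L))
  w <- numeric(n)
  for (i in seq_len(n)) {
    dens <- density_from_sqdist(dist_all[i, ], i, dataset$labels, params)
    c_i <- dataset$labels[i] + 1L
    d_center <- sqrt(sum((dataset$features[i, ] - centers[c_i, ])^2))
    w[i] <- dens$delta / (class_sizes[c_i] * max(d_center, params$epsilon))
  }
  if (!all(is.finite(w) & w > 0)) {
    imb_stop("imbfuse_format_error", "sample weights must be positive finite")
  }
  w
}

#' Target-neighbor pulls and impostor push triplets
#'
#' Pull pairs link each anchor to its `k_targets` nearest same-class
#' neighbors in the original space (distance ties broken by lower index);
#' they stay fixed through the optimization. Push triplets cross every pull
#' pair with every different-class sample, the literal full impostor
#' enumeration of the objective.
#'
#' @param dataset A [labeled_dataset()]; each class needs at least
#'   `k_targets + 1` samples.
#' @param k_targets Target-neighbor count.
#' @return Object of class `triplet_set`: list with `pull` (`P x 2` matrix of
#'   anchor/target indices) and `push` (`T x 3` matrix of
#'   anchor/target/impostor indices).
#' @export
build_triplets <- function(dataset, k_targets = 3L) {
  k_targets <- as.integer(k_targets)
  n <- nrow(dataset$features)
  labels <- dataset$labels
  for (cls in c(0L, 1L)) {
    if (sum(labels == cls) < k_targets + 1L) {
      imb_stop("imbfuse_insufficient_error",
               sprintf("class %d needs at least k_targets + 1 = %d samples",
                       cls, k_targets + 1L))
    }
  }
  d2 <- pairwise_sqdist(dataset$features)
  pull <- matrix(0L, nrow = n * k_targets, ncol = 2L)
  row <- 0L
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    # order by distance, ties by lower index
    nb <- same[order(d2[i, same], same, method = "radix")][seq_len(k_targets)]
    pull[row + seq_len(k_targets), ] <- cbind(i, nb)
    row <- row + k_targets
  }
  opp0 <- which(labels == 1L)  # impostors for majority anchors
  opp1 <- which(labels == 0L)
  push_list <- vector("list", nrow(pull))
  for (p in seq_len(nrow(pull))) {
    opp <- if (labels[pull[p, 1L]] == 0L) opp0 else opp1
    push_list[[p]] <- cbind(pull[p, 1L], pull[p, 2L], opp)
  }
  push <- do.call(rbind, push_list)
  colnames(pull) <- c("anchor", "target")
  colnames(push) <- c("anchor", "target", "impostor")
  structure(list(pull = pull, push = push), class = "triplet_set")
}

pair_sqdist_in <- function(z, a, b) {
  rowSums((z[a, , drop = FALSE] - z[b, , drop = FALSE])^2)
}

#' Weighted large-margin loss
#'
#' Evaluates the ImLMNN objective at a given linear map: the weighted pull
#' term over target-neighbor pairs plus the weighted hinge push term over
#' impostor triplets. With all weights equal to one this is the classic LMNN
#' loss (see [lmnn_loss()]).
#'
#' @param L A [linear_transform()] or plain `r x d` matrix.
#' @param dataset A [labeled_dataset()] (already in the space `L` acts on).
#' @param w Length-`n` positive anchor weights.
#' @param triplets A [build_triplets()] result.
#' @param margin Positive hinge margin.
#' @return Nonnegative scalar loss.
#' @export
imlmnn_loss <- function(L, dataset, w, triplets, margin = 1) {
  L <- as_transform_matrix(L)
  x <- dataset$features
  if (ncol(L) != ncol(x)) {
    imb_stop("imbfuse_dimension_error",
             sprintf("L has %d columns but data has %d features",
                     ncol(L), ncol(x)))
  }
  if (length(w) != nrow(x)) {
    imb_stop("imbfuse_dimension_error", "`w` must have one entry per sample")
  }
  z <- x %*% t(L)
  pull <- triplets$pull
  push <- triplets$push
  d2_pull <- pair_sqdist_in(z, pull[, 1L], pull[, 2L])
  loss_pull <- sum(w[pull[, 1L]] * d2_pull)
  d2_pt <- pair_sqdist_in(z, push[, 1L], push[, 2L])
  d2_pi <- pair_sqdist_in(z, push[, 1L], push[, 3L])
  hinge <- pmax(margin + d2_pt - d2_pi, 0)
  loss_pull + sum(w[push[, 1L]] * hinge)
}

#' Classic (unweighted) large-margin loss
#'
#' The ImLMNN objective with every anchor weight set to 1: the baseline used
#' by the `"lmnn"` ablation of the pipeline.
#'
#' @inheritParams imlmnn_loss
#' @return Nonnegative scalar loss.
#' @export
lmnn_loss <- function(L, dataset, triplets, margin = 1) {
  imlmnn_loss(L, dataset, rep(1, nrow(dataset$features)), triplets, margin)
}

#' Exact subgradient of the weighted large-margin loss
#'
#' Returns `2 L G` where `G` accumulates `w_i (x_i - x_j)(x_i - x_j)'` over
#' pull pairs and `w_i [(x_i - x_j)(x_i - x_j)' - (x_i - x_l)(x_i - x_l)']`
#' over push triplets whose hinge argument is strictly positive (triplets
#' exactly at the kink contribute nothing).
#'
#' @inheritParams imlmnn_loss
#' @return `r x d` gradient matrix.
#' @export
imlmnn_gradient <- function(L, dataset, w, triplets, margin = 1) {
  L <- as_transform_matrix(L)
  x <- dataset$features
  if (ncol(L) != ncol(x)) {
    imb_stop("imbfuse_dimension_error",
             sprintf("L has %d columns but data has %d features",
                     ncol(L), ncol(x)))
  }
  n <- nrow(x)
  z <- x %*% t(L)
  pull <- triplets$pull
  push <- triplets$push
  d2_pt <- pair_sqdist_in(z, push[, 1L], push[, 2L])
  d2_pi <- pair_sqdist_in(z, push[, 1L], push[, 3L])
  active <- (margin + d2_pt - d2_pi) > 0

  # accumulate pairwise coefficients c_ab on (a, b) pairs: the total
  # sum_ab c_ab (x_a - x_b)(x_a - x_b)' equals X' (Dr + Dc - M - M') X
  a <- c(pull[, 1L], push[active, 1L], push[active, 1L])
  b <- c(pull[, 2L], push[active, 2L], push[active, 3L])
  cc <- c(w[pull[, 1L]], w[push[active, 1L]], -w[push[active, 1L]])
  pair_id <- (a - 1) * n + b
  agg <- rowsum(cc, pair_id)
  m <- matrix(0, n, n)
  m[as.numeric(rownames(agg))] <- agg
  omega <- diag(rowSums(m) + colSums(m)) - m - t(m)
  unname(2 * L %*% crossprod(x, omega %*% x))
}

#' Fit the imbalance-weighted large-margin transform
#'
#' Optionally standardizes the features (training statistics only), computes
#' the anchor weights and the fixed triplet structure once in that space,
#' initializes `L` to the identity truncated to `output_dim` rows, and runs
#' gradient descent with per-iteration step halving: a step that would
#' increase the loss is halved and retried (up to 20 times), so the accepted
#' loss sequence is non-increasing by construction. Stops at `max_iters`,
#' when no halved step improves, or when the relative improvement falls
#' below `min_rel_improvement`.
#'
#' @param dataset A [labeled_dataset()] with both classes present.
#' @param config An [imlmnn_config()].
#' @param weighted If `FALSE`, all anchor weights are 1 and the fit is the
#'   classic LMNN baseline (see [fit_lmnn()]).
#' @return A [linear_transform()] carrying the learned map and the
#'   standardization; attributes `loss_history` (accepted losses, starting
#'   at the initialization) and `iterations`.
#' @export
fit_imlmnn <- function(dataset, config = imlmnn_config(), weighted = TRUE) {
  x <- dataset$features
  d <- ncol(x)
  center <- scale <- NULL
  if (isTRUE(config$standardize)) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale <= 0] <- 1
    x <- standardize_features(x, center, scale)
  }
  std <- labeled_dataset(x, dataset$labels,
                         feature_names = dataset$feature_names)
  w <- if (weighted) {
    sample_weights(std, config$density)
  } else {
    rep(1, nrow(x))
  }
  triplets <- build_triplets(std, config$k_targets)
  r <- as.integer(config$output_dim %||% d)
  if (r < 1L || r > d) {
    imb_stop("imbfuse_parameter_error", "need 1 <= output_dim <= d")
  }
  L <- diag(1, nrow = r, ncol = d)

  loss <- imlmnn_loss(L, std, w, triplets, config$margin)
  if (!is.finite(loss)) {
    imb_stop("imbfuse_divergence_error", "non-finite loss at initialization")
  }
  history <- loss
  iters <- 0L
  if (config$max_iters > 0L) {
    for (it in seq_len(config$max_iters)) {
      grad <- imlmnn_gradient(L, std, w, triplets, config$margin)
      step <- config$learning_rate
      accepted <- FALSE
      for (halving in 0:20) {
        cand <- L - step * grad
        cand_loss <- imlmnn_loss(cand, std, w, triplets, config$margin)
        if (is.finite(cand_loss) && cand_loss <= loss) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      rel <- (loss - cand_loss) / max(loss, .Machine$double.eps)
      L <- cand
      loss <- cand_loss
      history <- c(history, loss)
      iters <- it
      if (rel < config$min_rel_improvement) break
    }
  }
  out <- linear_transform(L, center = center, scale = scale)
  attr(out, "loss_history") <- history
  attr(out, "iterations") <- iters
  out
}

#' Fit the unweighted LMNN baseline transform
#'
#' Identical optimizer and triplet structure to [fit_imlmnn()] with all
#' anchor weights equal to 1; used by the `"lmnn"` ablation switch.
#'
#' @inheritParams fit_imlmnn
#' @return A [linear_transform()].
#' @export
fit_lmnn <- function(dataset, config = imlmnn_config()) {
  fit_imlmnn(dataset, config, weighted = FALSE)
}

#' Apply a fitted transform to a dataset
#'
#' Replays the standardization fitted during training (if any), then maps
#' every row through `L`. Labels are untouched.
#'
#' @param transform A [linear_transform()].
#' @param dataset A [labeled_dataset()] with matching feature dimension.
#' @return A [labeled_dataset()] with `r` transformed feature columns
#'   `z1..zr`.
#' @export
apply_transform <- function(transform, dataset) {
  stopifnot(inherits(transform, "linear_transform"))
  x <- dataset$features
  if (ncol(x) != ncol(transform$L)) {
    imb_stop("imbfuse_dimension_error",
             sprintf("transform expects %d features, data has %d",
                     ncol(transform$L), ncol(x)))
  }
  x <- standardize_features(x, transform$center, transform$scale)
  z <- x %*% t(transform$L)
  labeled_dataset(z, dataset$labels,
                  feature_names = paste0("z", seq_len(ncol(z))))
}

#' Mean anchor margin of a dataset
#'
#' For every sample, the distance to its nearest different-class sample
#' minus the distance to its nearest same-class sample; averaged over all
#' samples. A larger value means classes are locally better separated — the
#' quantity the large-margin transform is meant to improve.
#'
#' @param dataset A [labeled_dataset()] with both classes present.
#' @return Scalar mean margin.
#' @export
mean_anchor_margin <- function(dataset) {
  d2 <- pairwise_sqdist(dataset$features)
  diag(d2) <- Inf
  labels <- dataset$labels
  margins <- vapply(seq_along(labels), function(i) {
    same <- d2[i, labels == labels[i]]
    diff <- d2[i, labels != labels[i]]
    sqrt(min(diff)) - sqrt(min(same))
  }, numeric(1L))
  mean(margins)
}

#' Mean separation ratio of a dataset
#'
#' Scale-invariant companion to [mean_anchor_margin()]: for every sample,
#' the ratio of the distance to its nearest different-class sample over the
#' distance to its nearest same-class sample, averaged over samples. Unlike
#' the margin difference, the ratio is unchanged when the whole space is
#' rescaled, so it isolates the relative re-shaping a learned metric
#' performs from any global contraction or dilation.
#'
#' @param dataset A [labeled_dataset()] with both classes present.
#' @return Scalar mean ratio (`> 1` means classes are locally separated).
#' @export
mean_separation_ratio <- function(dataset) {
  d2 <- pairwise_sqdist(dataset$features)
  diag(d2) <- Inf
  labels <- dataset$labels
  ratios <- vapply(seq_along(labels), function(i) {
    same <- sqrt(min(d2[i, labels == labels[i]]))
    diff <- sqrt(min(d2[i, labels != labels[i]]))
    diff / max(same, .Machine$double.eps)
  }, numeric(1L))
  mean(ratios)
}

#' Write a linear transform to a delimited-text file
#'
#' Plain-text serialization: a header line with `r` and `d`, optional
#' `center`/`scale` lines, then the `r` rows of `L`, all floats at 17
#' significant digits for bit-stable round-trips.
#'
#' @param transform A [linear_transform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c(sprintf("r,d:%d,%d", nrow(transform$L), ncol(transform$L)),
             sprintf("center:%s",
                     if (is.null(transform$center)) "" else fmt(transform$center)),
             sprintf("scale:%s",
                     if (is.null(transform$scale)) "" else fmt(transform$scale)),
             apply(transform$L, 1L, fmt))
  writeLines(lines, path)
  invisible(path)
}

#' Read a linear transform written by [write_transform()]
#'
#' @param path Path to the transform file.
#' @return A [linear_transform()].
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dims <- as.integer(strsplit(sub("^r,d:", "", lines[1L]), ",")[[1L]])
  parse_vec <- function(line, tag) {
    body <- sub(paste0("^", tag, ":"), "", line)
    if (!nzchar(body)) NULL else as.numeric(strsplit(body, ",")[[1L]])
  }
  center <- parse_vec(lines[2L], "center")
  scale <- parse_vec(lines[3L], "scale")
  L <- do.call(rbind, lapply(lines[3L + seq_len(dims[1L])], function(l) {
    as.numeric(strsplit(l, ",")[[1L]])
  }))
  linear_transform(L, center = center, scale = scale)
}
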