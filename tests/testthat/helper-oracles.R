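# Independent brute-force oracles. These re-derive every quantity with
# plain loops and full sorts, sharing no code with the implementation paths
# they check.

# Euclidean distance between two rows, by explicit summation
slow_dist <- function(a, b) sqrt(sum((a - b)^2))

# target neighbors of anchor i: indices of the k nearest same-class rows,
# ties broken by lower index, via a full sort of all candidates
oracle_targets <- function(x, labels, i, k) {
  cand <- setdiff(which(labels == labels[i]), i)
  d <- vapply(cand, function(j) slow_dist(x[i, ], x[j, ]), numeric(1))
  cand[order(d, cand)][seq_len(k)]
}

# weighted large-margin loss by three nested loops
oracle_loss <- function(L, x, labels, w, k_targets, margin) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    targets <- oracle_targets(x, labels, i, k_targets)
    impostors <- which(labels != labels[i])
    for (j in targets) {
      dij <- sum((L %*% (x[i, ] - x[j, ]))^2)
      total <- total + w[i] * dij
      for (l in impostors) {
        dil <- sum((L %*% (x[i, ] - x[l, ]))^2)
        total <- total + w[i] * max(margin + dij - dil, 0)
      }
    }
  }
  total
}

# per-sample weights by straight-line re-evaluation of the definitions:
# density = inverse mean distance to k nearest majority / h nearest minority
# neighbors; weight = density / (class size * distance to own class mean)
oracle_weights <- function(x, labels, k, h, eps = 1e-12) {
  n <- nrow(x)
  w <- numeric(n)
  for (i in seq_len(n)) {
    d_maj <- sort(vapply(setdiff(which(labels == 0L), i),
                         function(j) slow_dist(x[i, ], x[j, ]), numeric(1)))
    d_min <- sort(vapply(setdiff(which(labels == 1L), i),
                         function(j) slow_dist(x[i, ], x[j, ]), numeric(1)))
    delta <- 1 / max(mean(d_maj[seq_len(k)]), eps) +
      1 / max(mean(d_min[seq_len(h)]), eps)
    own <- which(labels == labels[i])
    center <- colSums(x[own, , drop = FALSE]) / length(own)
    w[i] <- delta / (length(own) * max(slow_dist(x[i, ], center), eps))
  }
  w
}

# rank AUC by O(n^2) pair counting, ties worth one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# small random two-class dataset for oracle comparisons
random_instance <- function(n, d, seed, min_frac = 0.3) {
  set.seed(seed)
  n_min <- max(2L, round(n * min_frac))
  x <- matrix(rnorm(n * d), n, d)
  labels <- c(rep(0L, n - n_min), rep(1L, n_min))
  x[labels == 1L, 1L] <- x[labels == 1L, 1L] + 1.5
  labeled_dataset(x, labels)
}

# mirrored fixture: majority anchor A (row 1) and minority anchor P (row 5)
# have identical densities (k = h = 1) and identical unit distances to their
# own class means, so their weight ratio is exactly |N_maj| / |N_min| = 2
mirrored_fixture <- function() {
  x <- rbind(c(0, 0), c(2, 0), c(1, 2), c(1, -2),   # majority, mean (1, 0)
             c(-4, 0), c(-6, 0))                    # minority, mean (-5, 0)
  labeled_dataset(x, c(0L, 0L, 0L, 0L, 1L, 1L))
}

# 1-NN difference score: distance to nearest majority minus distance to
# nearest minority among the reference rows (larger = more minority-like)
one_nn_scores <- function(train, test) {
  vapply(seq_len(nrow(test$features)), function(i) {
    d <- vapply(seq_len(nrow(train$features)), function(j) {
      slow_dist(test$features[i, ], train$features[j, ])
    }, numeric(1))
    min(d[train$labels == 0L]) - min(d[train$labels == 1L])
  }, numeric(1))
}

# GA recovery fixture: member 1 ranks perfectly, members 2..5 are noise
perfect_member_fixture <- function(seed, n = 200L, n_pos = 40L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), c(n - n_pos, n_pos))
  scores <- cbind(labels + rnorm(n, sd = 0.01),
                  matrix(runif(n * 4), n, 4))
  list(scores = scores, labels = labels)
}
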