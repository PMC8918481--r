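# Genetic-algorithm search for the voting weights. A gene is a vector of S
# entries in [0, 1] (S = ensemble size); applied as voting weights it is
# normalized to the simplex. Fitness is the AUC of the weighted vote on a
# held-out validation slice. Replacement is elitist: a child replaces the
# current worst population member only on strict improvement, so the best
# fitness trajectory is non-decreasing by construction.

#' Genetic-algorithm configuration
#'
#' @param population_size Number of genes kept in the population (`>= 2`).
#' @param n_children Children generated per generation.
#' @param max_generations Generation cap (`>= 1`).
#' @param crossover_probability Probability a parent pair is crossed (single
#'   random position exchanged); otherwise children are copies.
#' @param mutation_probability Per-position probability that a child entry
#'   is replaced by a fresh uniform draw on `[0, 1]`.
#' @param stall_generations Early stop after this many generations without
#'   best-fitness improvement.
#' @param seed Integer seed; evolution is deterministic per seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, n_children = 30L,
                      max_generations = 100L, crossover_probability = 0.9,
                      mutation_probability = 0.1, stall_generations = 25L,
                      seed = 1L) {
  population_size <- as.integer(population_size)
  if (population_size < 2L || max_generations < 1L) {
    imb_stop("imbfuse_parameter_error",
             "need population_size >= 2 and max_generations >= 1")
  }
  structure(list(population_size = population_size,
                 n_children = as.integer(n_children),
                 max_generations = as.integer(max_generations),
                 crossover_probability = crossover_probability,
                 mutation_probability = mutation_probability,
                 stall_generations = as.integer(stall_generations),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Single-position crossover
#'
#' Exchanges exactly position `alpha` between two parent genes; all other
#' positions are inherited unchanged. Parents are not modified.
#'
#' @param g_i,g_j Parent genes (equal-length numeric vectors in `[0, 1]`).
#' @param alpha Exchange position in `1..S`.
#' @return List of the two child genes.
#' @export
crossover <- function(g_i, g_j, alpha) {
  s <- length(g_i)
  if (length(g_j) != s) {
    imb_stop("imbfuse_dimension_error", "parent genes must have equal length")
  }
  if (alpha < 1L || alpha > s) {
    imb_stop("imbfuse_parameter_error", "`alpha` out of range")
  }
  child_i <- g_i; child_j <- g_j
  child_i[alpha] <- g_j[alpha]
  child_j[alpha] <- g_i[alpha]
  list(child_i, child_j)
}

#' Single-position mutation
#'
#' Replaces position `gamma` with a fresh uniform draw on `[0, 1]`; all
#' other positions are unchanged.
#'
#' @param g Gene (numeric vector in `[0, 1]`).
#' @param gamma Mutation position in `1..S`.
#' @return The mutated gene.
#' @export
mutate <- function(g, gamma) {
  if (gamma < 1L || gamma > length(g)) {
    imb_stop("imbfuse_parameter_error", "`gamma` out of range")
  }
  g[gamma] <- stats::runif(1L)
  g
}

normalize_gene <- function(gene) {
  s <- sum(gene)
  if (s <= 0) rep(1 / length(gene), length(gene)) else gene / s
}

#' AUC fitness of a gene
#'
#' Normalizes the gene to the simplex (an all-zero gene falls back to
#' uniform weights), fuses the validation member scores by [weighted_vote()],
#' and returns the AUC of the fused score against the validation labels.
#'
#' @param gene Numeric gene vector in `[0, 1]^S`.
#' @param validation_scores `n x S` member score matrix on validation data.
#' @param validation_labels Length-`n` binary labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
ga_fitness <- function(gene, validation_scores, validation_labels) {
  auc_score(weighted_vote(as.matrix(validation_scores),
                          normalize_gene(gene)),
            validation_labels)
}

#' Evolve voting weights by elitist genetic search
#'
#' Initializes `population_size` genes uniformly at random on `[0, 1]^S`.
#' Each generation draws random parent pairs (uniform, without replacement
#' within a pair), applies single-position crossover with
#' `crossover_probability` and per-position mutation with
#' `mutation_probability`, evaluates the children, and lets each child that
#' strictly beats the current worst population member replace it. Stops at
#' `max_generations` or after `stall_generations` without best-fitness
#' improvement. With a single member (`S = 1`) the weight vector is trivially
#' `1` and no search runs.
#'
#' @param validation_scores `n x S` member score matrix.
#' @param validation_labels Length-`n` binary labels (both classes present).
#' @param config A [ga_config()].
#' @return List with `weights` (normalized best gene, on the simplex) and
#'   `state` (class `ga_state`: final `population` matrix, `fitness` vector
#'   and the non-decreasing `best_fitness_history`).
#' @export
evolve <- function(validation_scores, validation_labels,
                   config = ga_config()) {
  scores <- as.matrix(validation_scores)
  s <- ncol(scores)
  if (s == 1L) {
    fit <- auc_score(scores[, 1L], validation_labels)
    return(list(weights = 1,
                state = structure(list(population = matrix(1, 1L, 1L),
                                       fitness = fit,
                                       best_fitness_history = fit),
                                  class = "ga_state")))
  }
  np <- config$population_size
  with_seed(config$seed, {
    pop <- matrix(stats::runif(np * s), nrow = np, ncol = s)
    fitness <- apply(pop, 1L, ga_fitness, scores, validation_labels)
    history <- max(fitness)
    stall <- 0L
    for (gen in seq_len(config$max_generations)) {
      children <- matrix(0, nrow = 0L, ncol = s)
      while (nrow(children) < config$n_children) {
        pair <- sample.int(np, 2L)
        if (stats::runif(1L) < config$crossover_probability) {
          kids <- crossover(pop[pair[1L], ], pop[pair[2L], ],
                            sample.int(s, 1L))
        } else {
          kids <- list(pop[pair[1L], ], pop[pair[2L], ])
        }
        children <- rbind(children, kids[[1L]], kids[[2L]])
      }
      children <- children[seq_len(config$n_children), , drop = FALSE]
      for (h in seq_len(nrow(children))) {
        hit <- which(stats::runif(s) < config$mutation_probability)
        for (g in hit) children[h, ] <- mutate(children[h, ], g)
        child_fit <- ga_fitness(children[h, ], scores, validation_labels)
        worst <- which.min(fitness)
        if (child_fit > fitness[worst]) {
          pop[worst, ] <- children[h, ]
          fitness[worst] <- child_fit
        }
      }
      best <- max(fitness)
      stall <- if (best > history[length(history)]) 0L else stall + 1L
      history <- c(history, best)
      if (stall >= config$stall_generations) break
    }
    best_gene <- pop[which.max(fitness), ]
    list(weights = normalize_gene(best_gene),
         state = structure(list(population = pop, fitness = fitness,
                                best_fitness_history = history),
                           class = "ga_state"))
  })
}
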