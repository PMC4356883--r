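#' Genetic-search configuration for correlation-based feature selection
#'
#' Defaults (population 20, 20 generations, crossover 0.6, per-bit mutation
#' 0.033, tournament selection, elitism of one) follow the documented
#' defaults of the classic toolkit implementation of genetic search.
#'
#' @param population_size Number of bitstrings per generation.
#' @param n_generations Number of generations.
#' @param crossover_prob Probability of single-point crossover per pairing.
#' @param mutation_prob Per-bit mutation probability.
#' @param seed Integer seed.
#' @return A `cfs_config` list.
#' @export
cfs_config <- function(population_size = 20L, n_generations = 20L,
                       crossover_prob = 0.6, mutation_prob = 0.033,
                       seed = 1L) {
  stopifnot(population_size >= 1, n_generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 seed = as.integer(seed)),
            class = "cfs_config")
}

#' CFS merit of a descriptor subset
#'
#' The correlation-based feature selection merit
#' `k * rcf / sqrt(k + k * (k - 1) * rff)`, where `k` is the subset size,
#' `rcf` the mean absolute Pearson correlation between subset descriptors and
#' the target, and `rff` the mean absolute pairwise correlation within the
#' subset — rewarding target relevance, penalizing redundancy. Correlations
#' use pairwise-complete rows; a constant column's correlations are treated
#' as 0. The empty subset has merit 0.
#'
#' @param data A [compound_table()] (or data frame).
#' @param target Name of the target column.
#' @param subset Character vector of descriptor names.
#' @return The merit (a finite scalar).
#' @export
cfs_merit <- function(data, target, subset) {
  if (!length(subset)) return(0)
  pre <- precompute_cfs(data, target, features = subset)
  merit_from_cors(pre$rcf, pre$Rff, seq_along(subset))
}

# |correlation| structures reused across many merit evaluations.
precompute_cfs <- function(data, target, features = NULL) {
  if (is.null(features)) {
    features <- if (inherits(data, "compound_table")) feature_names(data)
                else setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                             c(target, "compound_id"))
  }
  X <- as.matrix(as.data.frame(data[features], check.names = FALSE))
  y <- data[[target]]
  suppressWarnings({
    rcf <- abs(as.numeric(cor(X, y, use = "pairwise.complete.obs")))
    Rff <- abs(cor(X, use = "pairwise.complete.obs"))
  })
  rcf[is.na(rcf)] <- 0
  Rff[is.na(Rff)] <- 0
  diag(Rff) <- 1
  list(features = features, rcf = setNames(rcf, features), Rff = Rff)
}

merit_from_cors <- function(rcf, Rff, idx) {
  k <- length(idx)
  if (k == 0L) return(0)
  mean_rcf <- mean(rcf[idx])
  mean_rff <- if (k == 1L) 0 else {
    sub <- Rff[idx, idx]
    (sum(sub) - k) / (k * (k - 1))
  }
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' Genetic search for the best-merit descriptor subset
#'
#' A bitstring genetic algorithm (one bit per descriptor) with CFS merit as
#' fitness: seeded random initialization, size-2 tournament selection,
#' single-point crossover, per-bit mutation and elitism of one. Returns the
#' best subset ever evaluated; reproducible under the configured seed.
#'
#' @param data A [compound_table()] (or data frame).
#' @param target Name of the target column.
#' @param config A [cfs_config()].
#' @param features Candidate descriptors (default: all feature columns).
#' @return A list with `names` (the selected subset, never empty) and
#'   `merit`.
#' @export
ga_search <- function(data, target, config = cfs_config(), features = NULL) {
  pre <- precompute_cfs(data, target, features)
  p <- length(pre$features)
  if (p == 0L) abort("No candidate descriptors.")
  if (p == 1L) {
    return(list(names = pre$features,
                merit = merit_from_cors(pre$rcf, pre$Rff, 1L)))
  }
  fitness <- function(bits) merit_from_cors(pre$rcf, pre$Rff, which(bits))
  with_local_seed(config$seed, {
    pop <- matrix(runif(config$population_size * p) < 0.5,
                  nrow = config$population_size)
    fit <- apply(pop, 1, fitness)
    best_bits <- pop[which.max(fit), ]
    best_fit <- max(fit)
    for (gen in seq_len(config$n_generations)) {
      nxt <- matrix(FALSE, config$population_size, p)
      nxt[1, ] <- pop[which.max(fit), ]  # elitism
      for (i in seq(2, config$population_size)) {
        pa <- tournament(fit)
        pb <- tournament(fit)
        child <- pop[pa, ]
        if (runif(1) < config$crossover_prob) {
          cut <- sample.int(p - 1L, 1L)
          child <- c(pop[pa, seq_len(cut)], pop[pb, (cut + 1L):p])
        }
        flip <- runif(p) < config$mutation_prob
        child[flip] <- !child[flip]
        nxt[i, ] <- child
      }
      pop <- nxt
      fit <- apply(pop, 1, fitness)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_bits <- pop[which.max(fit), ]
      }
    }
    if (!any(best_bits)) {  # all-noise data: fall back to best singleton
      best_bits[which.max(pre$rcf)] <- TRUE
      best_fit <- fitness(best_bits)
    }
    list(names = pre$features[best_bits], merit = best_fit)
  })
}

tournament <- function(fit) {
  idx <- sample.int(length(fit), 2L)
  idx[which.max(fit[idx])]
}

#' Exhaustive-search oracle for CFS
#'
#' Enumerates every non-empty subset of at most 15 descriptors and returns
#' the global merit maximizer; used as the independent oracle bounding
#' [ga_search()].
#'
#' @inheritParams ga_search
#' @return A list with `names` and `merit`.
#' @export
exhaustive_search <- function(data, target, features = NULL) {
  pre <- precompute_cfs(data, target, features)
  p <- length(pre$features)
  if (p > 15L) abort("Exhaustive search supports at most 15 descriptors.")
  best_merit <- -Inf
  best_idx <- integer(0)
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    m <- merit_from_cors(pre$rcf, pre$Rff, idx)
    if (m > best_merit) {
      best_merit <- m
      best_idx <- idx
    }
  }
  list(names = pre$features[best_idx], merit = best_merit)
}
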