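# GA individuals are lists of integer node-index vectors (one per cluster,
# sorted, no intra-cluster repeats; overlap between clusters allowed), with
# per-cluster fitness terms cached so mutation only recomputes the clusters
# it touched. Duplicate clusters (identical member sets) are counted once in
# the fitness (see density_fitness).

new_individual <- function(clusters_idx, net, objective) {
  clusters_idx <- lapply(clusters_idx, function(i) sort(unique(as.integer(i))))
  terms <- vapply(clusters_idx, function(i) cluster_term(net, i, objective),
                  numeric(1L))
  keys <- vapply(clusters_idx, paste, character(1L), collapse = ",")
  list(clusters = clusters_idx, terms = terms, keys = keys,
       fitness = sum(terms[!duplicated(keys)]))
}

refresh_individual <- function(ind, changed, net, objective) {
  for (j in changed) {
    i <- sort(unique(ind$clusters[[j]]))
    ind$clusters[[j]] <- i
    ind$terms[j] <- cluster_term(net, i, objective)
    ind$keys[j] <- paste(i, collapse = ",")
  }
  ind$fitness <- sum(ind$terms[!duplicated(ind$keys)])
  ind
}

#' Initialize a random GA population
#'
#' Each individual holds `k` clusters. Every cluster draws `ceiling(N/k)`
#' node indices uniformly with replacement from the network (repeats within a
#' cluster collapse; the same node landing in several clusters creates
#' overlap). Nodes left unassigned are then appended to a uniformly chosen
#' cluster, so every individual covers the network and the discard ratio of
#' the final prediction reflects post-processing, not initialization gaps.
#'
#' @inheritParams cut_weight
#' @param k Number of clusters per individual; at most the number of
#'   proteins.
#' @param pop_size Number of individuals (at least 2).
#' @param objective Fitness objective name, see [clustering_fitness()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A `ga_population` object (list of individuals with cached
#'   fitness).
#' @export
init_population_random <- function(net, k, pop_size, objective = "density",
                                   seed = NULL) {
  net <- as_ppi_network(net)
  k <- as.integer(k)
  pop_size <- as.integer(pop_size)
  if (k < 1L) stop("k must be >= 1")
  if (k > net$n) stop("k exceeds the number of proteins (", net$n, ")")
  if (pop_size < 2L) stop("population size must be >= 2")
  run <- function() {
    per <- ceiling(net$n / k)
    lapply(seq_len(pop_size), function(i) {
      cl <- lapply(seq_len(k), function(j) {
        unique(sample.int(net$n, per, replace = TRUE))
      })
      assigned <- unique(unlist(cl, use.names = FALSE))
      missing <- setdiff(seq_len(net$n), assigned)
      for (v in missing) {
        j <- sample.int(k, 1L)
        cl[[j]] <- c(cl[[j]], v)
      }
      new_individual(cl, net, objective)
    })
  }
  pop <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(pop, class = "ga_population", objective = objective)
}

#' Initialize a GA population from spectral clustering
#'
#' The first individual is exactly the recursive spectral clustering of the
#' network; each of the remaining `pop_size - 1` individuals is that
#' clustering perturbed by 1 to 3 applications of the mutation operator,
#' anchoring the population near the spectral solution while keeping
#' diversity.
#'
#' @inheritParams init_population_random
#' @param move_prob Probability the mutation moves a node between clusters
#'   rather than expanding a cluster by a member's network neighbors.
#' @param ... Passed to [spectral_cluster()] (`split_threshold`,
#'   `min_cluster_size`, `eig_tol`, `objective` is the *spectral* split score
#'   and is set separately there).
#' @export
init_population_spectral <- function(net, pop_size, objective = "density",
                                     move_prob = 0.5, seed = NULL, ...) {
  net <- as_ppi_network(net)
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L) stop("population size must be >= 2 (selection needs choice)")
  base_tb <- spectral_cluster(net, ...)
  base_idx <- lapply(clusters_as_list(base_tb), function(m) node_index(net, m))
  run <- function() {
    base <- new_individual(base_idx, net, objective)
    pop <- vector("list", pop_size)
    pop[[1L]] <- base
    for (i in seq_len(pop_size - 1L)) {
      ind <- base
      for (r in seq_len(sample.int(3L, 1L))) {
        ind <- mutate_individual(ind, net, objective, move_prob)
      }
      pop[[i + 1L]] <- ind
    }
    pop
  }
  pop <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(pop, class = "ga_population", objective = objective)
}

#' @export
print.ga_population <- function(x, ...) {
  f <- vapply(x, `[[`, numeric(1L), "fitness")
  cat(sprintf("<ga_population> %d individuals (%s fitness: best %.4f, mean %.4f)\n",
              length(x), attr(x, "objective"), max(f), mean(f)))
  invisible(x)
}

#' Fitness-proportionate parent selection
#'
#' Roulette-wheel sampling with replacement over shifted-positive fitness
#' values (population minimum subtracted, small epsilon added, so
#' non-positive fitnesses are handled); when all fitnesses are equal the
#' sampling is uniform. `method = "tournament"` instead picks each parent as
#' the best of `tournament_size` uniform draws.
#'
#' @param fitness Numeric vector of population fitnesses (higher is better).
#' @param n_parents Number of parents to draw.
#' @param method `"roulette"` (default) or `"tournament"`.
#' @param tournament_size Tournament size when `method = "tournament"`.
#' @return Integer vector of selected population indices.
#' @export
select_parents <- function(fitness, n_parents,
                           method = c("roulette", "tournament"),
                           tournament_size = 2L) {
  method <- match.arg(method)
  m <- length(fitness)
  stopifnot(m >= 1L, n_parents >= 0L)
  if (n_parents == 0L) return(integer())
  if (method == "tournament") {
    return(vapply(seq_len(n_parents), function(i) {
      cand <- sample.int(m, tournament_size, replace = TRUE)
      cand[which.max(fitness[cand])]
    }, integer(1L)))
  }
  shifted <- fitness - min(fitness)
  if (max(shifted) == 0) {
    prob <- rep(1 / m, m)
  } else {
    prob <- shifted + 1e-6 * max(shifted)
    prob <- prob / sum(prob)
  }
  sample.int(m, n_parents, replace = TRUE, prob = prob)
}

# Core mutation on an individual. Two moves, per the adapted operator:
#  * move:   one node occurrence, chosen uniformly over all (cluster, member)
#            pairs, is moved from its cluster to another uniformly chosen
#            cluster (no-op when k = 1);
#  * expand: one (cluster, member) occurrence is chosen uniformly and every
#            network neighbor of that member is added to the cluster -- the
#            overlap-creating move.
mutate_individual <- function(ind, net, objective, move_prob = 0.5) {
  sizes <- lengths(ind$clusters)
  if (all(sizes == 0L)) {
    warning("individual has only empty clusters; mutation skipped")
    return(ind)
  }
  k <- length(ind$clusters)
  # uniform over occurrences: cluster weighted by size, then member uniform
  src <- sample.int(k, 1L, prob = sizes / sum(sizes))
  member <- ind$clusters[[src]][sample.int(sizes[src], 1L)]
  if (stats::runif(1L) < move_prob) {
    if (k < 2L) return(ind)  # no target cluster: degenerate no-op
    tgt <- sample.int(k - 1L, 1L)
    tgt <- if (tgt >= src) tgt + 1L else tgt
    ind$clusters[[src]] <- setdiff(ind$clusters[[src]], member)
    ind$clusters[[tgt]] <- c(ind$clusters[[tgt]], member)
    refresh_individual(ind, c(src, tgt), net, objective)
  } else {
    ind$clusters[[src]] <- c(ind$clusters[[src]], net$adj[[member]])
    refresh_individual(ind, src, net, objective)
  }
}

#' Mutate a clustering
#'
#' Applies one GA mutation to a clustering: with probability `move_prob` a
#' uniformly chosen node occurrence is moved to another cluster; otherwise a
#' uniformly chosen (cluster, member) pair is expanded by adding all network
#' neighbors of that member to the cluster (this is the move that creates
#' overlap between clusters). Cluster sets stay valid: no duplicates within
#' a cluster, indices in range.
#'
#' @inheritParams init_population_random
#' @param clusters A clustering tibble (`cluster`, `protein`) or list of
#'   protein-ID vectors.
#' @param move_prob Probability of the move branch (default 0.5).
#' @return The mutated clustering as a tibble.
#' @export
mutate_clustering <- function(net, clusters, move_prob = 0.5, seed = NULL) {
  net <- as_ppi_network(net)
  idx <- lapply(clusters_as_list(clusters), function(m) node_index(net, m))
  ind <- new_individual(idx, net, "density")
  run <- function() mutate_individual(ind, net, "density", move_prob)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  members <- lapply(out$clusters, function(i) net$proteins[i])
  names(members) <- names(clusters_as_list(clusters))
  clusters_as_tibble(members)
}

#' Post-process a GA clustering into predicted complexes
#'
#' Drops empty clusters and clusters smaller than `min_size`, merges
#' duplicate clusters (identical member sets), and orders the result
#' canonically (members sorted; clusters by descending size then first
#' member).
#'
#' @param clusters A clustering tibble or list of protein-ID vectors.
#' @param min_size Minimum complex size kept (default 3, the usual convention
#'   for predicted protein complexes).
#' @return A tibble with columns `cluster` and `protein`; empty (0-row) with
#'   a warning if everything is filtered out.
#' @export
postprocess_clusters <- function(clusters, min_size = 3L) {
  members <- lapply(clusters_as_list(clusters), function(m) sort(unique(as.character(m))))
  members <- members[lengths(members) >= max(1L, min_size)]
  keys <- vapply(members, paste, character(1L), collapse = "\r")
  members <- members[!duplicated(keys)]
  if (!length(members)) {
    warning("no clusters survive post-processing")
    return(tibble::tibble(cluster = character(), protein = character()))
  }
  clusters_as_tibble(order_clusters(members))
}

#' Predict protein complexes with a genetic algorithm
#'
#' Evolves a population of candidate (possibly overlapping) clusterings of a
#' PPI network. Each generation the population is evaluated, the `elitism`
#' best individuals are copied unchanged, and the rest of the next generation
#' is filled with mutated copies of fitness-proportionally selected parents.
#' There is no crossover: mutation (node moves and neighbor expansions) is
#' the only variation operator. Elitism makes the best-fitness trace monotone
#' non-decreasing; the whole run is reproducible from `seed`.
#'
#' @inheritParams init_population_random
#' @param objective Fitness: `"density"` (default; see [density_fitness()])
#'   or a multiway cut (`"minmax"`, `"ratio"`, `"normalized"`).
#' @param init `"spectral"` (default) seeds the population from the
#'   recursive spectral clustering; `"random"` draws random individuals with
#'   `k` clusters each.
#' @param pop_size Population size `m` (default 80).
#' @param generations Generation budget (default 200).
#' @param k Cluster count for random initialization; defaults to
#'   `max(2, floor(N/10))` (about one cluster per ten proteins). Ignored for
#'   spectral initialization.
#' @param mutation_rate Probability a selected offspring is mutated (default
#'   1: with crossover absent, mutation is the only source of variation).
#' @param elitism Number of best individuals copied unchanged each
#'   generation (default 2).
#' @param move_prob Probability mutation moves a node rather than expanding
#'   by neighbors (default 0.5).
#' @param min_complex_size Minimum predicted complex size kept at
#'   post-processing (default 3).
#' @param stagnation Stop early after this many generations without
#'   best-fitness improvement (default 50; `Inf` disables).
#' @param selection `"roulette"` or `"tournament"`, see [select_parents()].
#' @param split_threshold,min_cluster_size,eig_tol Spectral initialization
#'   parameters, see [spectral_cluster()].
#' @param seed Integer seed making the run fully reproducible; `NULL` uses
#'   the current RNG state.
#' @return A `ga_fit` object: `clusters` (post-processed predicted complexes
#'   as a tibble), `best_fitness`, `raw_clusters` (the best individual before
#'   filtering), `trace` (per-generation best/mean fitness tibble), and the
#'   configuration. Supports [generics::tidy()], [generics::glance()], and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' sim <- simulate_planted_network(n_complexes = 3, size_range = c(5, 6),
#'                                 p_in = 1, p_out = 0, seed = 1)
#' fit <- ga_cluster(sim$network, pop_size = 10, generations = 5, seed = 1)
#' glance(fit)
ga_cluster <- function(net,
                       objective = c("density", "minmax", "ratio", "normalized"),
                       init = c("spectral", "random"),
                       pop_size = 80L, generations = 200L, k = NULL,
                       mutation_rate = 1.0, elitism = 2L, move_prob = 0.5,
                       min_complex_size = 3L, stagnation = 50L,
                       selection = c("roulette", "tournament"),
                       split_threshold = 1.0, min_cluster_size = 1L,
                       eig_tol = 1e-8, seed = NULL) {
  objective <- match.arg(objective)
  init <- match.arg(init)
  selection <- match.arg(selection)
  net <- as_ppi_network(net)
  pop_size <- as.integer(pop_size)
  generations <- as.integer(generations)
  elitism <- as.integer(elitism)
  stopifnot(pop_size >= 2L, generations >= 1L,
            elitism >= 1L, elitism < pop_size,
            mutation_rate >= 0, mutation_rate <= 1,
            move_prob >= 0, move_prob <= 1)
  if (is.null(k)) k <- max(2L, net$n %/% 10L)

  run <- function() {
    pop <- if (init == "spectral") {
      init_population_spectral(net, pop_size, objective, move_prob,
                               split_threshold = split_threshold,
                               min_cluster_size = min_cluster_size,
                               eig_tol = eig_tol)
    } else {
      init_population_random(net, k, pop_size, objective)
    }
    fitness <- vapply(pop, `[[`, numeric(1L), "fitness")
    best_i <- which.max(fitness)
    best_ever <- pop[[best_i]]
    trace_best <- numeric(generations)
    trace_mean <- numeric(generations)
    stagnant <- 0L
    gen_run <- 0L
    for (g in seq_len(generations)) {
      ord <- order(fitness, decreasing = TRUE)
      elites <- pop[ord[seq_len(elitism)]]
      parents <- select_parents(fitness, pop_size - elitism, method = selection)
      offspring <- lapply(parents, function(i) {
        if (stats::runif(1L) < mutation_rate) {
          mutate_individual(pop[[i]], net, objective, move_prob)
        } else {
          pop[[i]]
        }
      })
      pop <- c(elites, offspring)
      fitness <- vapply(pop, `[[`, numeric(1L), "fitness")
      gen_best <- max(fitness)
      trace_best[g] <- gen_best
      trace_mean[g] <- mean(fitness)
      gen_run <- g
      if (gen_best > best_ever$fitness + 1e-12) {
        best_ever <- pop[[which.max(fitness)]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      if (stagnant >= stagnation) break
    }
    list(best = best_ever,
         trace = tibble::tibble(generation = seq_len(gen_run),
                                best_fitness = trace_best[seq_len(gen_run)],
                                mean_fitness = trace_mean[seq_len(gen_run)]))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  raw_members <- lapply(res$best$clusters, function(i) net$proteins[i])
  raw_members <- raw_members[lengths(raw_members) > 0L]
  predicted <- suppressWarnings(postprocess_clusters(raw_members, min_complex_size))
  structure(
    list(
      clusters = predicted,
      raw_clusters = clusters_as_tibble(order_clusters(raw_members)),
      best_fitness = res$best$fitness,
      trace = res$trace,
      objective = objective,
      init = init,
      config = list(pop_size = pop_size, generations = generations, k = k,
                    mutation_rate = mutation_rate, elitism = elitism,
                    move_prob = move_prob, min_complex_size = min_complex_size,
                    stagnation = stagnation, selection = selection,
                    split_threshold = split_threshold,
                    min_cluster_size = min_cluster_size, seed = seed),
      n_proteins = net$n
    ),
    class = "ga_fit"
  )
}

#' @export
print.ga_fit <- function(x, ...) {
  nc <- length(unique(x$clusters$cluster))
  cat(sprintf("<ga_fit> %s objective, %s init: best fitness %.4f after %d generations\n",
              x$objective, x$init, x$best_fitness, nrow(x$trace)))
  cat(sprintf("  %d predicted complexes (min size %d), covering %d of %d proteins\n",
              nc, x$config$min_complex_size,
              length(unique(x$clusters$protein)), x$n_proteins))
  invisible(x)
}
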