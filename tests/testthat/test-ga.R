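test_that("random initialization is seeded, covering, and diverse", {
  sim <- simulate_planted_network(p_in = 1, p_out = 0, seed = 5)
  net <- sim$network

  p1 <- init_population_random(net, k = 10, pop_size = 50, seed = 9)
  p2 <- init_population_random(net, k = 10, pop_size = 50, seed = 9)
  expect_identical(p1, p2)

  # every individual covers the whole network
  for (ind in p1[1:5]) {
    expect_setequal(unlist(ind$clusters), seq_len(net$n))
    expect_true(all(vapply(ind$clusters, anyDuplicated, integer(1)) == 0L))
  }
  expect_gt(population_diversity(p1), 0)

  # k = 1: the single cluster holds everything
  pk1 <- init_population_random(net, k = 1, pop_size = 3, seed = 1)
  expect_equal(pk1[[1]]$clusters[[1]], seq_len(net$n))

  expect_error(init_population_random(net, k = net$n + 1, pop_size = 5),
               "exceeds")
  expect_error(init_population_random(net, k = 2, pop_size = 1), ">= 2")
})

test_that("spectral initialization anchors at the spectral solution", {
  expect_error(init_population_spectral(path_net(4), pop_size = 1), ">= 2")

  net <- clique_union_net(c(5, 6, 7))
  pop <- init_population_spectral(net, pop_size = 10, seed = 3,
                                  split_threshold = 0.5)
  # first individual is the exact spectral clustering: one term per clique
  expect_equal(pop[[1]]$fitness, 3)

  # spectral start is at least as fit as a random start on planted fixtures
  wins <- vapply(1:20, function(s) {
    sim <- simulate_planted_network(seed = 2000 + s)
    ps <- init_population_spectral(sim$network, 20, seed = s)
    pr <- init_population_random(sim$network, 10, 20, seed = s)
    max(vapply(ps, `[[`, numeric(1), "fitness")) >=
      max(vapply(pr, `[[`, numeric(1), "fitness"))
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("roulette selection is fitness-proportionate after the shift", {
  draws <- withr::with_seed(21, {
    replicate(1000, select_parents(c(10, 0, 0, 0), 1))
  })
  expect_gte(mean(draws == 1), 0.9)

  eq <- withr::with_seed(22, select_parents(c(2, 2), 1e4))
  expect_lt(abs(mean(eq == 1) - 0.5), 0.05)

  # degenerate all-equal fitness: uniform over the population
  u <- withr::with_seed(23, select_parents(rep(0, 4), 4000))
  expect_true(all(abs(tabulate(u, 4) / 4000 - 0.25) < 0.05))

  tw <- withr::with_seed(24, select_parents(c(1, 5, 3), 500, method = "tournament"))
  expect_gt(mean(tw == 2), mean(tw == 1))
})

test_that("mutation semantics: neighbor expansion and node moves", {
  # star fixture: center with 3 outside neighbors; expansion adds exactly 3
  star <- edge_net(c("hub","x", "hub","y", "hub","z"))
  out <- mutate_clustering(star, list(c("hub")), move_prob = 0, seed = 1)
  expect_setequal(out$protein, c("hub", "x", "y", "z"))

  # expansion is idempotent when all neighbors are already in the cluster
  tri <- complete_net(3)
  cl <- list(letters[1:3])
  out2 <- mutate_clustering(tri, cl, move_prob = 0, seed = 2)
  expect_setequal(out2$protein, letters[1:3])

  # move on a single-cluster individual is a no-op
  out3 <- mutate_clustering(tri, cl, move_prob = 1, seed = 3)
  expect_setequal(out3$protein, letters[1:3])
  expect_equal(length(unique(out3$cluster)), 1L)

  # mutation output always stays a valid clustering
  net <- gnp_net(12, 0.4, 61)
  ind <- init_population_random(net, 3, 2, seed = 8)[[1]]
  for (s in 1:50) {
    ind <- withr::with_seed(s, mutate_individual(ind, net, "density", 0.5))
    idx <- unlist(ind$clusters)
    if (length(idx)) {
      expect_true(min(idx) >= 1 && max(idx) <= net$n)
    }
    expect_true(all(vapply(ind$clusters, anyDuplicated, integer(1)) == 0L))
    # cached fitness stays in sync with a fresh recomputation
    expect_equal(ind$fitness,
                 density_fitness(net, lapply(ind$clusters,
                                             function(i) net$proteins[i])))
  }
})

test_that("evolution is elitist, monotone, and reproducible", {
  sim <- simulate_planted_network(n_complexes = 3, size_range = c(6, 6),
                                  p_in = 0.9, p_out = 0.05, seed = 17)
  f1 <- ga_cluster(sim$network, pop_size = 12, generations = 15, seed = 5)
  f2 <- ga_cluster(sim$network, pop_size = 12, generations = 15, seed = 5)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$clusters, f2$clusters)
  expect_true(all(diff(f1$trace$best_fitness) >= 0))

  # one generation never loses the initial best (elitism)
  init_best <- max(vapply(init_population_spectral(sim$network, 12, seed = 5),
                          `[[`, numeric(1), "fitness"))
  g1 <- ga_cluster(sim$network, pop_size = 12, generations = 1, seed = 5)
  expect_gte(g1$best_fitness, init_best)
})

test_that("the GA attains the exhaustive partition optimum on small graphs", {
  hits <- vapply(1:20, function(s) {
    net <- gnp_net(7, 0.5, 860 + s)
    best <- oracle_best_partition_jd(adj_matrix(net))$value
    fit <- ga_cluster(net, init = "random", k = 3, pop_size = 20,
                      generations = 60, min_complex_size = 1, seed = s)
    fit$best_fitness >= best - 1e-9
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("overlapping planted complexes yield overlapping predictions", {
  sim <- simulate_planted_network(n_complexes = 2, size_range = c(8, 8),
                                  p_in = 1, p_out = 0, overlap_pairs = 1,
                                  shared_count = 2, seed = 71)
  fit <- ga_cluster(sim$network, pop_size = 40, generations = 150, seed = 1)
  cl <- split(fit$clusters$protein, fit$clusters$cluster)
  overlaps <- utils::combn(length(cl), 2, function(ij) {
    length(intersect(cl[[ij[1]]], cl[[ij[2]]]))
  })
  expect_true(any(overlaps > 0))
})

test_that("post-processing filters, merges, and orders deterministically", {
  out <- postprocess_clusters(list(c("a", "b", "c"), c("c", "b", "a"), "d"),
                              min_size = 3)
  expect_equal(unique(out$cluster), "C1")
  expect_equal(sort(out$protein), c("a", "b", "c"))

  keep <- list(c("a", "b", "c"), c("d", "e", "f", "g"))
  out2 <- postprocess_clusters(keep, min_size = 3)
  expect_equal(unname(lapply(split(out2$protein, out2$cluster), sort)),
               list(c("d", "e", "f", "g"), c("a", "b", "c")))  # size-desc order

  expect_warning(empty <- postprocess_clusters(list("a"), min_size = 3),
                 "no clusters")
  expect_equal(nrow(empty), 0L)
})

test_that("clique fixtures: fitness reaches the planted optimum and counts match", {
  stats <- vapply(1:20, function(s) {
    sim <- simulate_planted_network(p_in = 1, p_out = 0.02, seed = 5000 + s)
    fit <- ga_cluster(sim$network, pop_size = 80, generations = 200, seed = s)
    truth_jd <- density_fitness(sim$network, sim$complexes)
    c(attained = fit$best_fitness >= 0.95 * truth_jd,
      count_ok = abs(length(unique(fit$clusters$cluster)) - 6) <= 2)
  }, numeric(2))
  expect_gte(sum(stats["attained", ]), 18)
  expect_gte(sum(stats["count_ok", ]), 15)
})

test_that("tidiers and plots summarize a fit faithfully", {
  sim <- simulate_planted_network(n_complexes = 3, size_range = c(5, 5),
                                  p_in = 1, p_out = 0, seed = 2)
  fit <- ga_cluster(sim$network, pop_size = 10, generations = 10, seed = 4)
  td <- tidy(fit)
  expect_equal(sum(td$size), nrow(fit$clusters))
  gl <- glance(fit)
  expect_equal(gl$best_fitness, fit$best_fitness)
  expect_equal(gl$n_complexes, length(unique(fit$clusters$cluster)))
  expect_s3_class(autoplot(fit), "ggplot")
})
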