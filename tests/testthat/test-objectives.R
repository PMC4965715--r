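test_that("cut weight counts crossing edges exactly", {
  p4 <- path_net(4)
  expect_equal(cut_weight(p4, c("a", "b"), c("c", "d")), 1)
  expect_equal(cut_weight(p4, c("c", "d"), c("a", "b")), 1)  # symmetric

  tri2 <- clique_union_net(c(3, 3))
  blocks <- clique_blocks(c(3, 3))
  expect_equal(cut_weight(tri2, blocks[[1]], blocks[[2]]), 0)

  expect_error(cut_weight(p4, c("a", "zz"), "b"), "unknown protein")

  # brute-force edge scan oracle on random graphs and bipartitions
  for (s in 1:5) {
    net <- gnp_net(12, 0.4, 120 + s)
    A <- adj_matrix(net)
    i1 <- withr::with_seed(s, sample(12, 5))
    i2 <- setdiff(1:12, i1)
    expect_equal(cut_weight(net, net$proteins[i1], net$proteins[i2]),
                 sum(A[i1, i2]))
  }
})

test_that("two-way objectives match their formulas on a path", {
  p4 <- path_net(4)
  v1 <- c("a", "b")
  v2 <- c("c", "d")
  expect_equal(minmax_cut(p4, v1, v2), 2)       # 1/1 + 1/1
  expect_equal(ratio_cut(p4, v1, v2), 1)        # 1/2 + 1/2
  expect_equal(normalized_cut(p4, v1, v2), 2 / 3)  # 1/3 + 1/3
})

test_that("zero-cut component splits score 0 under every objective", {
  net <- clique_union_net(c(4, 4))
  blocks <- clique_blocks(c(4, 4))
  expect_equal(minmax_cut(net, blocks[[1]], blocks[[2]]), 0)
  expect_equal(ratio_cut(net, blocks[[1]], blocks[[2]]), 0)
  expect_equal(normalized_cut(net, blocks[[1]], blocks[[2]]), 0)
})

test_that("objectives agree with the matrix oracle over all bipartitions", {
  for (s in 1:3) {
    net <- gnp_net(9, 0.5, 300 + s)
    A <- adj_matrix(net)
    for (bp in all_bipartitions(9)) {
      v1 <- net$proteins[bp[[1]]]
      v2 <- net$proteins[bp[[2]]]
      expect_equal(minmax_cut(net, v1, v2),
                   oracle_two_way(A, bp[[1]], bp[[2]], "minmax"))
      expect_equal(ratio_cut(net, v1, v2),
                   oracle_two_way(A, bp[[1]], bp[[2]], "ratio"))
      jn <- normalized_cut(net, v1, v2)
      expect_equal(jn, oracle_two_way(A, bp[[1]], bp[[2]], "normalized"))
      if (is.finite(jn)) {
        expect_gte(jn, 0)
        expect_lte(jn, 2)
      }
    }
  }
})

test_that("density fitness is exact on cliques, paths, and a frozen instance", {
  net <- clique_union_net(c(4, 5, 6))
  expect_equal(density_fitness(net, clique_blocks(c(4, 5, 6))), 3)

  p3 <- path_net(3)
  expect_equal(density_fitness(p3, list(c("a", "b", "c"))), 2 / 3)

  # frozen value: exhaustive <=3-block partition maximum on G(8, 0.5),
  # seed 801 (13 edges), computed with the matrix-enumeration oracle
  net8 <- gnp_net(8, 0.5, 801)
  res <- oracle_best_partition_jd(adj_matrix(net8), max_blocks = 3)
  expect_equal(res$value, 1.057142857143, tolerance = 1e-10)
  expect_equal(
    density_fitness(net8, lapply(res$blocks, function(i) net8$proteins[i])),
    res$value
  )
})

test_that("density fitness terms are bounded, label-invariant, dedup duplicates", {
  for (s in 1:5) {
    net <- gnp_net(10, 0.4, 550 + s)
    blocks <- withr::with_seed(s, {
      a <- sample(3, 10, replace = TRUE)
      split(net$proteins, a)
    })
    st <- cluster_stats(net, blocks)
    ratio <- ifelse(st$max_edges + st$w_boundary > 0,
                    st$w_in / (st$max_edges + st$w_boundary), 0)
    expect_true(all(ratio >= 0 & ratio <= 1))
    expect_equal(density_fitness(net, blocks), sum(ratio))
    expect_lte(density_fitness(net, blocks), sum(lengths(blocks) > 1))
    # invariant to cluster order
    expect_equal(density_fitness(net, rev(blocks)),
                 density_fitness(net, blocks))
    # d_k = 2 W_kk + W_ki for whole-network degrees
    expect_equal(st$degree_mass, 2 * st$w_in + st$w_boundary)
  }
  # duplicated clusters are counted once
  net <- complete_net(3)
  expect_equal(density_fitness(net, list(letters[1:3], letters[1:3])), 1)
  # singleton clusters contribute 0
  expect_equal(density_fitness(net, list(letters[1:3], "a")), 1)
})

test_that("multiway fitness reduces to the two-way objectives for k = 2", {
  for (s in 1:4) {
    net <- gnp_net(8, 0.5, 700 + s)
    i1 <- withr::with_seed(s, sample(8, 4))
    i2 <- setdiff(1:8, i1)
    v1 <- net$proteins[i1]
    v2 <- net$proteins[i2]
    cl <- list(v1, v2)
    # the reduction holds whenever denominators are positive; degenerate
    # sides are scored Inf two-way but 0 multiway, by the different
    # zero-denominator policies
    if (is.finite(minmax_cut(net, v1, v2))) {
      expect_equal(multiway_cut_fitness(net, cl, "minmax"),
                   -minmax_cut(net, v1, v2))
    }
    expect_equal(multiway_cut_fitness(net, cl, "ratio"),
                 -ratio_cut(net, v1, v2))
    expect_equal(multiway_cut_fitness(net, cl, "normalized"),
                 -normalized_cut(net, v1, v2))
  }
  net <- clique_union_net(c(3, 4))
  bl <- clique_blocks(c(3, 4))
  for (kind in c("minmax", "ratio", "normalized")) {
    expect_equal(multiway_cut_fitness(net, bl, kind), 0)
  }
})

test_that("multiway terms match direct recomputation on a random clustering", {
  net <- gnp_net(11, 0.4, 901)
  A <- adj_matrix(net)
  blocks <- withr::with_seed(41, {
    lapply(1:3, function(j) sample(net$proteins, sample(3:6, 1)))
  })
  idx <- lapply(blocks, function(m) sort(match(m, net$proteins)))
  keys <- vapply(idx, paste, character(1), collapse = ",")
  idx <- idx[!duplicated(keys)]
  for (kind in c("minmax", "ratio", "normalized")) {
    expected <- -sum(vapply(idx, function(i) {
      W <- sum(A[i, i]) / 2
      Wki <- sum(A[i, -i, drop = FALSE])
      den <- switch(kind, minmax = W, ratio = length(i),
                    normalized = sum(A[i, ]))
      if (den > 0) Wki / den else 0
    }, numeric(1)))
    expect_equal(multiway_cut_fitness(net, blocks, kind), expected)
  }
})
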