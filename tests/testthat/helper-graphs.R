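# Small graph builders used across tests. All deterministic given their
# arguments.

# network from flat vector c("a","b", "b","c") of edge endpoints
edge_net <- function(pairs, proteins = NULL) {
  m <- matrix(pairs, ncol = 2L, byrow = TRUE)
  as_ppi_network(data.frame(from = m[, 1L], to = m[, 2L]), proteins = proteins)
}

path_net <- function(n) {
  ids <- letters[seq_len(n)]
  edge_net(as.vector(rbind(ids[-n], ids[-1L])), proteins = ids)
}

complete_net <- function(n, ids = letters[seq_len(n)]) {
  pr <- utils::combn(ids, 2L)
  edge_net(as.vector(pr), proteins = ids)
}

# disjoint union of cliques with given sizes; ids V01, V02, ...
clique_union_net <- function(sizes) {
  n <- sum(sizes)
  ids <- sprintf("V%02d", seq_len(n))
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  pairs <- character()
  for (b in seq_along(sizes)) {
    memb <- ids[off[b] + seq_len(sizes[b])]
    if (sizes[b] >= 2L) pairs <- c(pairs, as.vector(utils::combn(memb, 2L)))
  }
  edge_net(pairs, proteins = ids)
}

clique_blocks <- function(sizes) {
  ids <- sprintf("V%02d", seq_len(sum(sizes)))
  split(ids, rep(seq_along(sizes), sizes))
}

# Erdos-Renyi G(n, p) on letters, seeded
gnp_net <- function(n, p, seed) {
  ids <- letters[seq_len(n)]
  withr::with_seed(seed, {
    pr <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(pr)) < p
    as_ppi_network(data.frame(from = ids[pr[1L, keep]], to = ids[pr[2L, keep]]),
                   proteins = ids)
  })
}

adj_matrix <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight"))
}

# fraction of nodes assigned to the majority-matching side of a bisection
block_agreement <- function(sides, truth) {
  a <- mean(c(truth[[1L]] %in% sides[[1L]], truth[[2L]] %in% sides[[2L]]))
  max(a, 1 - a)
}
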