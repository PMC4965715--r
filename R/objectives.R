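#' Cut weight between two node sets
#'
#' Total weight of edges with one endpoint in `v1` and the other in `v2`
#' (unit weights unless the network carries weights). Symmetric in its
#' arguments.
#'
#' @param net A [ppi_network][as_ppi_network].
#' @param v1,v2 Protein IDs (or 1-based indices) of the two sets.
#' @return A non-negative number.
#' @export
cut_weight <- function(net, v1, v2) {
  net <- as_ppi_network(net)
  i1 <- unique(node_index(net, v1))
  i2 <- unique(node_index(net, v2))
  in1 <- logical(net$n); in1[i1] <- TRUE
  in2 <- logical(net$n); in2[i2] <- TRUE
  ends <- igraph::as_edgelist(net$graph, names = FALSE)
  cross <- (in1[ends[, 1L]] & in2[ends[, 2L]]) | (in2[ends[, 1L]] & in1[ends[, 2L]])
  sum(net$weights[cross])
}

# Internal per-subgraph bipartition quantities.
# W11/W22: internal edge weights; W12: crossing weight; d1/d2: degree mass of
# each side *within the induced subgraph on v1 ∪ v2* (so recursive bisection
# is self-similar).
bipartition_stats <- function(net, i1, i2) {
  in1 <- logical(net$n); in1[i1] <- TRUE
  in2 <- logical(net$n); in2[i2] <- TRUE
  ends <- igraph::as_edgelist(net$graph, names = FALSE)
  w <- net$weights
  e1 <- in1[ends[, 1L]]; e2 <- in2[ends[, 1L]]
  f1 <- in1[ends[, 2L]]; f2 <- in2[ends[, 2L]]
  W11 <- sum(w[e1 & f1])
  W22 <- sum(w[e2 & f2])
  W12 <- sum(w[(e1 & f2) | (e2 & f1)])
  list(W11 = W11, W22 = W22, W12 = W12,
       d1 = 2 * W11 + W12, d2 = 2 * W22 + W12)
}

check_bipartition <- function(net, v1, v2) {
  i1 <- unique(node_index(net, v1))
  i2 <- unique(node_index(net, v2))
  if (!length(i1) || !length(i2)) stop("both sides of a bipartition must be non-empty")
  if (length(intersect(i1, i2))) stop("bipartition sides must be disjoint")
  list(i1 = i1, i2 = i2)
}

# Zero-denominator policy for the two-way objectives: a zero denominator with
# a non-zero numerator is the worst possible split, reported as Inf (never a
# crash); 0/0 contributes 0.
two_way_term <- function(num, den) {
  if (den > 0) return(num / den)
  if (num == 0) 0 else Inf
}

#' Two-way cut objectives
#'
#' Scores a bipartition `(V1, V2)` of a (sub)graph. With `W_ij` the edge
#' weight between the sides, `|V_i|` the side sizes and `d_i` the degree mass
#' of side `i` within the induced subgraph on `V1 U V2`:
#' \deqn{JM = W12/W11 + W12/W22 \quad (Min-Max cut)}
#' \deqn{JR = W12/|V1| + W12/|V2| \quad (Ratio cut)}
#' \deqn{JN = W12/d1 + W12/d2 \quad (Normalized cut)}
#' Lower is better; all are 0 for a zero-cut split. A zero denominator with a
#' non-zero cut returns `Inf` (worst possible split).
#'
#' @inheritParams cut_weight
#' @return A non-negative number (possibly `Inf`).
#' @export
minmax_cut <- function(net, v1, v2) {
  net <- as_ppi_network(net)
  p <- check_bipartition(net, v1, v2)
  s <- bipartition_stats(net, p$i1, p$i2)
  two_way_term(s$W12, s$W11) + two_way_term(s$W12, s$W22)
}

#' @rdname minmax_cut
#' @export
ratio_cut <- function(net, v1, v2) {
  net <- as_ppi_network(net)
  p <- check_bipartition(net, v1, v2)
  s <- bipartition_stats(net, p$i1, p$i2)
  s$W12 / length(p$i1) + s$W12 / length(p$i2)
}

#' @rdname minmax_cut
#' @export
normalized_cut <- function(net, v1, v2) {
  net <- as_ppi_network(net)
  p <- check_bipartition(net, v1, v2)
  s <- bipartition_stats(net, p$i1, p$i2)
  two_way_term(s$W12, s$d1) + two_way_term(s$W12, s$d2)
}

two_way_objective <- function(net, v1, v2, objective) {
  switch(objective,
    minmax = minmax_cut(net, v1, v2),
    ratio = ratio_cut(net, v1, v2),
    normalized = normalized_cut(net, v1, v2),
    stop("unknown two-way objective: ", objective)
  )
}

#' Per-cluster edge statistics
#'
#' For each cluster `C_k`: its size, internal edge count `W_kk`, boundary
#' count `W_ki` (edges with exactly one endpoint in `C_k`, counted against the
#' whole network), the maximum possible internal edge count
#' `A_k = |C_k|(|C_k|-1)/2`, and the whole-network degree mass `d_k` of its
#' members. With overlapping clusters an edge may contribute to several
#' clusters' boundaries.
#'
#' @inheritParams cut_weight
#' @param clusters A clustering: tibble with `cluster`/`protein` columns or a
#'   list of protein-ID vectors.
#' @return A tibble with one row per cluster.
#' @export
cluster_stats <- function(net, clusters) {
  net <- as_ppi_network(net)
  members <- clusters_as_list(clusters)
  idx <- lapply(members, function(m) unique(node_index(net, m)))
  rows <- lapply(idx, function(i) cluster_raw_stats(net, i))
  nm <- names(members)
  if (is.null(nm) || !all(nzchar(nm))) nm <- paste0("C", seq_along(members))
  tibble::tibble(
    cluster = nm,
    size = vapply(rows, `[[`, numeric(1L), "size"),
    w_in = vapply(rows, `[[`, numeric(1L), "W_kk"),
    w_boundary = vapply(rows, `[[`, numeric(1L), "W_ki"),
    max_edges = vapply(rows, `[[`, numeric(1L), "A_k"),
    degree_mass = vapply(rows, `[[`, numeric(1L), "d_k")
  )
}

# Fast path used by the GA: counts on unit weights via adjacency lists.
# cnt_in counts every internal edge twice.
cluster_raw_stats <- function(net, idx) {
  s <- length(idx)
  if (s == 0L) {
    return(list(size = 0, W_kk = 0, W_ki = 0, A_k = 0, d_k = 0))
  }
  in_c <- logical(net$n)
  in_c[idx] <- TRUE
  cnt_in <- 0L
  adj <- net$adj
  for (v in idx) cnt_in <- cnt_in + sum(in_c[adj[[v]]])
  d_k <- sum(net$deg[idx])
  list(size = s, W_kk = cnt_in / 2, W_ki = d_k - cnt_in,
       A_k = s * (s - 1) / 2, d_k = d_k)
}

# One JD term: W_kk / (A_k + W_ki); zero denominator (singleton/empty
# cluster) contributes 0.
jd_term <- function(net, idx) {
  st <- cluster_raw_stats(net, idx)
  den <- st$A_k + st$W_ki
  if (den > 0) st$W_kk / den else 0
}

multiway_term <- function(net, idx, kind) {
  st <- cluster_raw_stats(net, idx)
  den <- switch(kind,
    minmax = st$W_kk,
    ratio = st$size,
    normalized = st$d_k
  )
  if (den > 0) -st$W_ki / den else 0
}

cluster_term <- function(net, idx, objective) {
  if (objective == "density") jd_term(net, idx) else multiway_term(net, idx, objective)
}

# Distinct clusters only: identical member sets are merged before summing, so
# replicating one dense cluster does not inflate the fitness.
distinct_index_sets <- function(idx_list) {
  idx_list <- lapply(idx_list, function(i) sort(unique(i)))
  keys <- vapply(idx_list, paste, character(1L), collapse = ",")
  idx_list[!duplicated(keys)]
}

#' Density-based clustering fitness
#'
#' The GA's default fitness. Each cluster contributes
#' \deqn{W_{kk} / (A_k + W_{ki}),} the ratio of its internal edges to the sum
#' of its maximum possible internal edges and its boundary edges; the fitness
#' is the sum over distinct clusters. Each term lies in `[0, 1]` and reaches 1
#' exactly for an isolated clique, so dense well-separated clusters score
#' high. Singleton and empty clusters contribute 0. Higher is better.
#'
#' @inheritParams cluster_stats
#' @return A non-negative number.
#' @export
density_fitness <- function(net, clusters) {
  net <- as_ppi_network(net)
  idx <- lapply(clusters_as_list(clusters), function(m) node_index(net, m))
  idx <- distinct_index_sets(idx)
  sum(vapply(idx, function(i) jd_term(net, i), numeric(1L)))
}

#' Multiway cut fitness
#'
#' Generalizes the two-way cut objectives to a k-cluster (possibly
#' overlapping) clustering as \eqn{\sum_k W_{ki} / D_k}, with denominator
#' `D_k` the internal edge count (`minmax`), the cluster size (`ratio`), or
#' the whole-network degree mass (`normalized`). The sum is negated so that,
#' like [density_fitness()], higher is better for every GA fitness function.
#' Zero-denominator terms contribute 0.
#'
#' @inheritParams cluster_stats
#' @param kind One of `"minmax"`, `"ratio"`, `"normalized"`.
#' @return A non-positive number (0 for perfectly separated clusters).
#' @export
multiway_cut_fitness <- function(net, clusters, kind = c("minmax", "ratio", "normalized")) {
  kind <- match.arg(kind)
  net <- as_ppi_network(net)
  idx <- lapply(clusters_as_list(clusters), function(m) node_index(net, m))
  idx <- distinct_index_sets(idx)
  sum(vapply(idx, function(i) multiway_term(net, i, kind), numeric(1L)))
}

#' Clustering fitness under a named objective
#'
#' Dispatches to [density_fitness()] (`"density"`) or
#' [multiway_cut_fitness()]. All objectives are oriented so higher is better.
#'
#' @inheritParams cluster_stats
#' @param objective One of `"density"`, `"minmax"`, `"ratio"`, `"normalized"`.
#' @return A number.
#' @export
clustering_fitness <- function(net, clusters,
                               objective = c("density", "minmax", "ratio", "normalized")) {
  objective <- match.arg(objective)
  if (objective == "density") density_fitness(net, clusters)
  else multiway_cut_fitness(net, clusters, objective)
}
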