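#' Laplacian and degree matrix of an induced subgraph
#'
#' Returns the combinatorial Laplacian `Q = D - A` and the diagonal degree
#' matrix `D` of the subgraph induced on `nodes`, the pair appearing in the
#' generalized eigenproblem `Q x = lambda D x` that relaxes the normalized
#' cut. Rows/columns are ordered and named by the nodes as given.
#'
#' @inheritParams cut_weight
#' @param nodes Protein IDs (or indices) of the subgraph; at least 2.
#' @return A list with dense matrices `Q` and `D`.
#' @export
laplacian_pair <- function(net, nodes) {
  net <- as_ppi_network(net)
  idx <- unique(node_index(net, nodes))
  if (length(idx) < 2L) stop("subgraph needs at least 2 nodes")
  sub <- igraph::induced_subgraph(net$graph, idx)
  A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight", sparse = TRUE))
  d <- rowSums(A)
  if (all(d == 0)) stop("subgraph has no edges; unsplittable")
  Q <- diag(d, nrow = nrow(A)) - A
  D <- diag(d, nrow = nrow(A))
  dimnames(Q) <- dimnames(A)
  dimnames(D) <- dimnames(A)
  list(Q = Q, D = D)
}

#' Fiedler vector of the generalized Laplacian problem
#'
#' Solves `Q x = lambda D x` for the eigenvector at the smallest positive
#' eigenvalue (the Fiedler vector), via the similarity transform to the
#' symmetric normalized Laplacian `D^{-1/2} Q D^{-1/2}`. Requires the
#' subgraph to be connected (callers pre-split components). The vector is
#' D-normalized (`x' D x = 1`) and the sign is fixed so its first component
#' of largest magnitude is positive, making results deterministic.
#'
#' @param Q,D Matrices from [laplacian_pair()].
#' @param tol Residual tolerance: the solve fails if
#'   `||Qx - lambda D x|| > tol * ||Q||`.
#' @return A named numeric vector, with the eigenvalue in attribute
#'   `"lambda"`.
#' @export
fiedler_vector <- function(Q, D, tol = 1e-8) {
  d <- diag(D)
  if (any(d <= 0)) stop("isolated vertex in subgraph; pre-split components first")
  dh <- 1 / sqrt(d)
  Lsym <- Q * tcrossprod(dh)           # D^{-1/2} Q D^{-1/2}
  Lsym <- (Lsym + t(Lsym)) / 2
  es <- eigen(Lsym, symmetric = TRUE)
  n <- nrow(Q)
  lambda <- es$values[n - 1L]          # second-smallest: Fiedler value
  y <- es$vectors[, n - 1L]
  x <- dh * y
  x <- x / sqrt(sum(d * x^2))          # x' D x = 1
  pivot <- which.max(abs(x))
  if (x[pivot] < 0) x <- -x
  resid <- sqrt(sum((Q %*% x - lambda * (d * x))^2))
  if (resid > tol * max(1, norm(Q, "F"))) {
    stop(sprintf("eigensolver residual %.3e exceeds tolerance %.3e", resid, tol))
  }
  names(x) <- rownames(Q)
  attr(x, "lambda") <- lambda
  x
}

# Deterministic 1-D 2-means: centroids start at min(x) and max(x), assignment
# ties break toward the lower-mean centroid, run to convergence.
kmeans1d_2 <- function(x) {
  c1 <- min(x)
  c2 <- max(x)
  if (c1 == c2) return(NULL)  # constant vector: caller falls back
  assign_old <- rep(NA, length(x))
  for (it in seq_len(100L)) {
    lo <- min(c1, c2); hi <- max(c1, c2)
    a <- ifelse(abs(x - lo) <= abs(x - hi), 1L, 2L)
    if (identical(a, assign_old)) break
    assign_old <- a
    if (!any(a == 1L) || !any(a == 2L)) break
    c1 <- mean(x[a == 1L])
    c2 <- mean(x[a == 2L])
  }
  a
}

#' Spectral bisection of a node set
#'
#' Computes the Fiedler vector of the induced subgraph and partitions the
#' nodes by 1-D 2-means on its components (deterministic min/max
#' initialization). Disconnected node sets are split along the largest
#' component boundary without touching the eigensolver. If the Fiedler
#' vector is constant, the split falls back to index parity with a warning.
#'
#' @inheritParams laplacian_pair
#' @param eig_tol Eigensolver residual tolerance, see [fiedler_vector()].
#' @return A list of two character vectors of protein IDs, both non-empty.
#' @export
spectral_bisect <- function(net, nodes = NULL, eig_tol = 1e-8) {
  net <- as_ppi_network(net)
  idx <- if (is.null(nodes)) seq_len(net$n) else unique(node_index(net, nodes))
  if (length(idx) < 2L) stop("need at least 2 nodes to bisect")
  comp <- subgraph_components(net, idx)
  if (length(comp) > 1L) {
    side1 <- comp[[1L]]
    side2 <- unlist(comp[-1L], use.names = FALSE)
    return(list(net$proteins[side1], net$proteins[side2]))
  }
  lp <- laplacian_pair(net, idx)
  x <- fiedler_vector(lp$Q, lp$D, tol = eig_tol)
  a <- kmeans1d_2(as.numeric(x))
  if (is.null(a)) {
    warning("constant Fiedler vector; falling back to index-parity split")
    a <- rep_len(c(1L, 2L), length(idx))
  }
  list(net$proteins[idx[a == 1L]], net$proteins[idx[a == 2L]])
}

# Connected components of the induced subgraph, as lists of whole-network
# indices, largest first (ties by smallest member index for determinism).
subgraph_components <- function(net, idx) {
  sub <- igraph::induced_subgraph(net$graph, idx)
  memb <- igraph::components(sub)$membership
  comp <- split(idx[order(seq_along(idx))], memb)
  comp <- unname(comp)
  comp <- lapply(comp, sort)
  firsts <- vapply(comp, `[[`, integer(1L), 1L)
  comp[order(-lengths(comp), firsts)]
}

#' Recursive spectral clustering
#'
#' Builds an exclusive clustering of the whole network by recursive spectral
#' bisection: connected components are always separated first; a connected
#' block is bisected along its Fiedler vector, and the split is accepted
#' while its two-way objective value stays below `split_threshold` and both
#' children have at least `min_cluster_size` nodes. The number and size of
#' clusters is thus set by the network topology and the threshold, not
#' pre-specified. Deterministic given its arguments.
#'
#' @inheritParams cut_weight
#' @param objective Two-way objective scoring each candidate split:
#'   `"normalized"` (default; the eigenproblem is its relaxation),
#'   `"minmax"`, or `"ratio"`.
#' @param split_threshold Keep splitting while the objective value of the
#'   accepted bisection is below this (default 1.0 for the normalized cut,
#'   whose value on a bipartition lies in `[0, 2]`).
#' @param min_cluster_size Reject splits producing a side smaller than this.
#' @param eig_tol Eigensolver residual tolerance.
#' @return A tibble with columns `cluster` and `protein`; every protein
#'   appears in exactly one cluster.
#' @export
spectral_cluster <- function(net, objective = c("normalized", "minmax", "ratio"),
                             split_threshold = 1.0, min_cluster_size = 1L,
                             eig_tol = 1e-8) {
  objective <- match.arg(objective)
  stopifnot(split_threshold > 0, min_cluster_size >= 1L)
  net <- as_ppi_network(net)
  blocks <- spectral_partition(net, objective, split_threshold,
                               min_cluster_size, eig_tol)
  members <- lapply(blocks, function(i) net$proteins[i])
  clusters_as_tibble(order_clusters(members))
}

# Core recursion on integer index sets; returns list of index vectors.
spectral_partition <- function(net, objective, split_threshold,
                               min_cluster_size, eig_tol) {
  out <- list()
  recurse <- function(idx) {
    if (length(idx) < 2L) {
      out[[length(out) + 1L]] <<- idx
      return(invisible())
    }
    comp <- subgraph_components(net, idx)
    if (length(comp) > 1L) {
      for (c_ in comp) recurse(c_)
      return(invisible())
    }
    if (length(idx) < 2L * min_cluster_size) {
      out[[length(out) + 1L]] <<- idx
      return(invisible())
    }
    lp <- laplacian_pair(net, idx)
    x <- fiedler_vector(lp$Q, lp$D, tol = eig_tol)
    a <- kmeans1d_2(as.numeric(x))
    if (is.null(a)) a <- rep_len(c(1L, 2L), length(idx))
    v1 <- idx[a == 1L]
    v2 <- idx[a == 2L]
    if (!length(v1) || !length(v2)) {
      out[[length(out) + 1L]] <<- idx
      return(invisible())
    }
    val <- two_way_objective(net, net$proteins[v1], net$proteins[v2], objective)
    if (val < split_threshold &&
        length(v1) >= min_cluster_size && length(v2) >= min_cluster_size) {
      recurse(v1)
      recurse(v2)
    } else {
      out[[length(out) + 1L]] <<- idx
    }
  }
  recurse(seq_len(net$n))
  out
}
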