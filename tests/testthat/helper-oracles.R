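# Independent oracles: everything here recomputes quantities from the dense
# adjacency matrix (or by direct summation), never through the package's
# adjacency-list code paths.

# all set partitions of 1..n as restricted-growth assignment vectors
all_set_partitions <- function(n, max_blocks = n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(min(mx + 1L, max_blocks))) rec(c(a, v), max(mx, v))
  }
  rec(integer(), 0L)
  out
}

# JD fitness of a clustering given as a list of index vectors, from the
# adjacency matrix
oracle_jd <- function(A, blocks) {
  total <- 0
  for (i in blocks) {
    s <- length(i)
    if (s < 1L) next
    W <- sum(A[i, i]) / 2
    Wki <- sum(A[i, -i, drop = FALSE])
    Ak <- s * (s - 1) / 2
    if (Ak + Wki > 0) total <- total + W / (Ak + Wki)
  }
  total
}

# exhaustive JD maximum over set partitions (optionally block-limited)
oracle_best_partition_jd <- function(A, max_blocks = nrow(A)) {
  n <- nrow(A)
  best <- -Inf
  best_blocks <- NULL
  for (a in all_set_partitions(n, max_blocks)) {
    blocks <- split(seq_len(n), a)
    v <- oracle_jd(A, blocks)
    if (v > best) {
      best <- v
      best_blocks <- blocks
    }
  }
  list(value = best, blocks = best_blocks)
}

# two-way objectives from the adjacency matrix restricted to i1 U i2
oracle_two_way <- function(A, i1, i2, kind) {
  W11 <- sum(A[i1, i1]) / 2
  W22 <- sum(A[i2, i2]) / 2
  W12 <- sum(A[i1, i2, drop = FALSE])
  term <- function(num, den) {
    if (den > 0) num / den else if (num == 0) 0 else Inf
  }
  switch(kind,
    minmax = term(W12, W11) + term(W12, W22),
    ratio = W12 / length(i1) + W12 / length(i2),
    normalized = term(W12, 2 * W11 + W12) + term(W12, 2 * W22 + W12)
  )
}

# all bipartitions of 1..n (node 1 fixed to side 1 to halve the count)
all_bipartitions <- function(n) {
  out <- list()
  for (mask in seq_len(2^(n - 1L) - 1L)) {
    side2 <- which(bitwAnd(bitwShiftL(1L, seq_len(n - 1L) - 1L), mask) != 0L) + 1L
    out[[length(out) + 1L]] <- list(setdiff(seq_len(n), side2), side2)
  }
  out
}

# hypergeometric upper tail by direct summation of binomial-coefficient
# ratios: P(X >= k) = sum_{i >= k} C(M,i) C(N-M,n-i) / C(N,n), the
# complement of the 1 - sum_{i < k} form but free of cancellation; all
# coefficients are exact in double precision for N <= 30
oracle_hyper <- function(N, M, n, k) {
  if (k == 0) return(1)
  i <- k:min(M, n)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# mean pairwise Jaccard distance between individuals' sets of clusters
# (each cluster canonicalized to a sorted-index key)
population_diversity <- function(pop) {
  sets <- lapply(pop, function(ind) {
    unique(vapply(ind$clusters, function(i) paste(sort(i), collapse = ","),
                  character(1L)))
  })
  pairs <- utils::combn(length(sets), 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- sets[[ij[1L]]]
    b <- sets[[ij[2L]]]
    1 - length(intersect(a, b)) / length(union(a, b))
  }))
}
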