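#' Simulate a planted-complex benchmark network
#'
#' Generates a PPI network with known ground-truth complexes: complex sizes
#' are drawn uniformly from `size_range`; designated complex pairs share
#' `shared_count` proteins (planted overlap); every protein pair that shares
#' a complex is connected with probability `p_in` and every other pair with
#' probability `p_out` (independent Bernoulli draws, so the graph is simple
#' by construction); `n_filler` background proteins belong to no complex.
#' Protein IDs are zero-padded (`P0001`, ...) for stable lexicographic
#' ordering. Fully reproducible from `seed`.
#'
#' The defaults reproduce the benchmark condition used throughout the
#' package's tests: six complexes of ten proteins, dense inside
#' (`p_in = 0.8`) and sparse between (`p_out = 0.02`).
#'
#' @param n_complexes Number of planted complexes (default 6).
#' @param size_range Length-2 integer vector of min/max complex size
#'   (default `c(10, 10)`).
#' @param p_in Intra-complex edge probability (default 0.8).
#' @param p_out Background edge probability (default 0.02); must be below
#'   `p_in`.
#' @param overlap_pairs Number of complex pairs sharing proteins (default 0).
#' @param shared_count Proteins shared by each overlapping pair (default 2);
#'   must be smaller than the minimum complex size.
#' @param n_filler Background proteins in no complex (default 0).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `network` (a [ppi_network][as_ppi_network]) and
#'   `complexes` (ground-truth catalog tibble with `complex`, `protein`).
#' @export
#' @examples
#' sim <- simulate_planted_network(n_complexes = 3, size_range = c(5, 8),
#'                                 p_in = 0.9, p_out = 0.01, seed = 42)
#' graph_stats(sim$network)
simulate_planted_network <- function(n_complexes = 6L, size_range = c(10L, 10L),
                                     p_in = 0.8, p_out = 0.02,
                                     overlap_pairs = 0L, shared_count = 2L,
                                     n_filler = 0L, seed = NULL) {
  n_complexes <- as.integer(n_complexes)
  size_range <- as.integer(size_range)
  stopifnot(n_complexes >= 1L, length(size_range) == 2L,
            size_range[1L] >= 2L, size_range[1L] <= size_range[2L],
            p_in > 0, p_in <= 1, p_out >= 0, p_out < p_in,
            overlap_pairs >= 0L, n_filler >= 0L)
  if (overlap_pairs > n_complexes %/% 2L) {
    stop("overlap_pairs exceeds the number of disjoint complex pairs available")
  }
  if (overlap_pairs > 0L && shared_count >= size_range[1L]) {
    stop("shared_count must be smaller than the minimum complex size")
  }
  run <- function() {
    size_choices <- seq.int(size_range[1L], size_range[2L])
    sizes <- size_choices[sample.int(length(size_choices), n_complexes,
                                     replace = TRUE)]
    # allocate node indices; overlapping pairs (1,2), (3,4), ... share the
    # first shared_count nodes of the earlier complex
    complexes <- vector("list", n_complexes)
    next_id <- 1L
    for (i in seq_len(n_complexes)) {
      partner_share <- integer()
      if (overlap_pairs > 0L && i %% 2L == 0L && i %/% 2L <= overlap_pairs) {
        partner_share <- complexes[[i - 1L]][seq_len(shared_count)]
      }
      fresh <- sizes[i] - length(partner_share)
      complexes[[i]] <- c(partner_share, seq.int(next_id, length.out = fresh))
      next_id <- next_id + fresh
    }
    n_nodes <- next_id - 1L + n_filler
    ids <- sprintf("P%04d", seq_len(n_nodes))
    in_complex <- matrix(FALSE, n_nodes, n_complexes)
    for (i in seq_len(n_complexes)) in_complex[complexes[[i]], i] <- TRUE
    # all unordered pairs; intra if the pair co-occurs in >= 1 complex
    pr <- utils::combn(n_nodes, 2L)
    intra <- rowSums(in_complex[pr[1L, ], , drop = FALSE] &
                     in_complex[pr[2L, ], , drop = FALSE]) > 0L
    prob <- ifelse(intra, p_in, p_out)
    # one uniform per pair: a higher edge probability at the same seed can
    # only add edges, never remove them
    keep <- stats::runif(length(prob)) < prob
    edges <- data.frame(from = ids[pr[1L, keep]], to = ids[pr[2L, keep]],
                        stringsAsFactors = FALSE)
    net <- as_ppi_network(edges, proteins = ids)
    truth <- tibble::tibble(
      complex = rep(sprintf("K%02d", seq_len(n_complexes)),
                    lengths(complexes)),
      protein = ids[unlist(complexes, use.names = FALSE)]
    )
    list(network = net, complexes = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a simulated benchmark to disk
#'
#' Writes the network as a TSV edge list and the ground-truth catalog in the
#' name-plus-members dialect read back by [read_edge_list()] and
#' [read_reference_complexes()].
#'
#' @param sim A list from [simulate_planted_network()].
#' @param network_path,complexes_path Output paths.
#' @return `sim`, invisibly.
#' @export
write_planted_network <- function(sim, network_path, complexes_path) {
  el <- igraph::as_edgelist(sim$network$graph, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), network_path)
  ref <- split(sim$complexes$protein, sim$complexes$complex)
  writeLines(vapply(names(ref), function(nm) {
    paste(c(nm, sort(ref[[nm]])), collapse = "\t")
  }, character(1L)), complexes_path)
  invisible(sim)
}
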