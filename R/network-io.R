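#' PPI network container
#'
#' A `ppi_network` wraps an undirected simple [igraph][igraph::igraph-package]
#' graph over named proteins together with the derived structures the
#' clustering machinery needs repeatedly: a 1-based protein index, adjacency
#' lists over indices, and whole-network degrees. Self-loops and duplicate
#' edges are removed on construction.
#'
#' @param x An edge-list data frame (two protein-ID columns, optional numeric
#'   weight column), an igraph object, or a `ppi_network`.
#' @param proteins Optional character vector fixing the full protein set and
#'   its order; proteins absent from the edge list become isolated nodes.
#'   Defaults to order of first appearance in the edge list.
#' @param ... Passed on to methods.
#'
#' @return A `ppi_network` object.
#' @export
#' @examples
#' edges <- tibble::tibble(from = c("A", "B"), to = c("B", "C"))
#' net <- as_ppi_network(edges)
#' graph_stats(net)
as_ppi_network <- function(x, ...) UseMethod("as_ppi_network")

#' @rdname as_ppi_network
#' @export
as_ppi_network.ppi_network <- function(x, ...) x

#' @rdname as_ppi_network
#' @export
as_ppi_network.data.frame <- function(x, proteins = NULL, ...) {
  if (ncol(x) < 2L) {
    stop("edge list needs at least two columns (interacting protein IDs)")
  }
  from <- as.character(x[[1L]])
  to <- as.character(x[[2L]])
  w <- if (ncol(x) >= 3L && is.numeric(x[[3L]])) as.numeric(x[[3L]]) else NULL
  new_ppi_network(from, to, weights = w, proteins = proteins)
}

#' @rdname as_ppi_network
#' @export
as_ppi_network.igraph <- function(x, ...) {
  if (igraph::is_directed(x)) {
    x <- igraph::as_undirected(x, mode = "collapse")
  }
  ends <- igraph::as_edgelist(x, names = TRUE)
  nm <- igraph::V(x)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(x)))
  new_ppi_network(as.character(ends[, 1L]), as.character(ends[, 2L]),
                  proteins = nm)
}

# Internal constructor: dedupes edges, drops self-loops (with a warning),
# freezes the protein index, precomputes adjacency lists and degrees.
new_ppi_network <- function(from, to, weights = NULL, proteins = NULL) {
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
  }
  lf <- from[!loops]
  lt <- to[!loops]
  lw <- if (is.null(weights)) NULL else weights[!loops]
  if (is.null(proteins)) {
    proteins <- unique(c(rbind(from, to)))
  } else {
    proteins <- as.character(proteins)
    if (anyDuplicated(proteins)) stop("duplicate protein IDs in `proteins`")
    missing <- setdiff(unique(c(lf, lt)), proteins)
    if (length(missing)) {
      stop("edge endpoints not in `proteins`: ", paste(missing, collapse = ", "))
    }
  }
  # canonical unordered pairs for dedup
  a <- pmin(lf, lt)
  b <- pmax(lf, lt)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep]
  b <- b[keep]
  lw <- if (is.null(lw)) rep(1, length(a)) else lw[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = lw, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = proteins, stringsAsFactors = FALSE)
  )
  build_ppi_network(g)
}

build_ppi_network <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  structure(
    list(
      graph = g,
      proteins = igraph::V(g)$name,
      n = n,
      n_edges = igraph::ecount(g),
      adj = adj,
      deg = vapply(adj, length, integer(1L)),
      weights = igraph::E(g)$weight
    ),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n", x$n, x$n_edges))
  invisible(x)
}

# Map protein IDs (or indices) to validated integer indices.
node_index <- function(net, nodes) {
  if (is.numeric(nodes)) {
    idx <- as.integer(nodes)
    if (length(idx) && (min(idx) < 1L || max(idx) > net$n)) {
      stop("node index out of range 1..", net$n)
    }
    return(idx)
  }
  idx <- match(as.character(nodes), net$proteins)
  if (anyNA(idx)) {
    stop("unknown protein ID(s): ",
         paste(unique(nodes[is.na(idx)]), collapse = ", "))
  }
  idx
}

read_noncomment_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a PPI network from a delimited edge list
#'
#' Each non-comment, non-blank line holds two protein IDs (an interaction) and
#' an optional numeric weight. Lines starting with `#` are ignored. Duplicate
#' edges collapse; self-loops are dropped with a warning. The order of first
#' appearance fixes the protein index.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator; defaults to any whitespace.
#' @return A [ppi_network][as_ppi_network] object.
#' @export
read_edge_list <- function(path, delimiter = NULL) {
  parsed <- read_noncomment_lines(path)
  lines <- parsed$lines
  nonblank <- nzchar(trimws(lines))
  lines <- lines[nonblank]
  lineno <- parsed$lineno[nonblank]
  if (!length(lines)) stop("empty edge list: ", path)
  split_re <- if (is.null(delimiter)) "\\s+" else delimiter
  fields <- strsplit(trimws(lines), split_re)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed edge list line %d in %s (need >= 2 fields)",
                 lineno[which(nf < 2L)[1L]], path))
  }
  from <- vapply(fields, `[[`, character(1L), 1L)
  to <- vapply(fields, `[[`, character(1L), 2L)
  w <- rep(NA_real_, length(fields))
  has_w <- nf >= 3L
  w[has_w] <- suppressWarnings(
    as.numeric(vapply(fields[has_w], `[[`, character(1L), 3L))
  )
  weights <- if (all(has_w) && !anyNA(w)) w else NULL
  new_ppi_network(from, to, weights = weights)
}

#' Basic graph statistics
#'
#' Average degree is `2E/N`; density is the ratio of realized to potential
#' interactions, `E / (N(N-1)/2)`.
#'
#' @param net A [ppi_network][as_ppi_network] (or anything coercible).
#' @return A one-row tibble with `n_proteins`, `n_edges`, `avg_degree`,
#'   `density`.
#' @export
graph_stats <- function(net) {
  net <- as_ppi_network(net)
  if (net$n < 2L) stop("density undefined for networks with fewer than 2 proteins")
  n <- net$n
  e <- net$n_edges
  tibble::tibble(
    n_proteins = n,
    n_edges = e,
    avg_degree = 2 * e / n,
    density = e / (n * (n - 1) / 2)
  )
}

#' Read a reference complex catalog
#'
#' MIPS/CYC2008-style plain text: one complex per line, the complex name
#' followed by its member protein IDs, whitespace-delimited. `#` comment lines
#' are ignored. Duplicate members within one complex are removed with a
#' warning; a repeated complex name is an error.
#'
#' @param path Path to the catalog file.
#' @return A tibble with columns `complex` and `protein`, one row per member.
#' @export
read_reference_complexes <- function(path) {
  parsed <- read_noncomment_lines(path)
  lines <- parsed$lines
  nonblank <- nzchar(trimws(lines))
  lines <- lines[nonblank]
  lineno <- parsed$lineno[nonblank]
  if (!length(lines)) stop("empty complex catalog: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed catalog line %d in %s (need name + >= 1 member)",
                 lineno[which(nf < 2L)[1L]], path))
  }
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate complex name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  members <- lapply(fields, function(f) f[-1L])
  ndup <- sum(vapply(members, anyDuplicated, integer(1L)) > 0L)
  if (ndup > 0L) {
    warning(sprintf("%d complex(es) listed duplicate members; deduplicated", ndup))
    members <- lapply(members, unique)
  }
  tibble::tibble(
    complex = rep(names_, lengths(members)),
    protein = unlist(members, use.names = FALSE)
  )
}

# Coerce a clustering given as a tibble (cluster, protein), a list of
# character/integer vectors, or a ga_fit, into a list of protein-ID vectors.
clusters_as_list <- function(clusters) {
  if (inherits(clusters, "ga_fit")) {
    clusters <- clusters$clusters
  }
  if (is.data.frame(clusters)) {
    grp_col <- intersect(c("cluster", "complex"), names(clusters))[1L]
    if (is.na(grp_col) || !"protein" %in% names(clusters)) {
      stop("clustering tibble needs columns `cluster` (or `complex`) and `protein`")
    }
    grp <- clusters[[grp_col]]
    return(split(as.character(clusters$protein),
                 factor(grp, levels = unique(grp))))
  }
  if (is.list(clusters)) return(clusters)
  stop("cannot interpret `clusters` as a clustering")
}

clusters_as_tibble <- function(members_list, prefix = "C") {
  nm <- names(members_list)
  if (is.null(nm) || !all(nzchar(nm))) {
    nm <- paste0(prefix, seq_along(members_list))
  }
  tibble::tibble(
    cluster = rep(nm, lengths(members_list)),
    protein = as.character(unlist(members_list, use.names = FALSE))
  )
}

# Canonical deterministic ordering: members sorted lexicographically,
# clusters by descending size then first member.
order_clusters <- function(members_list) {
  members_list <- lapply(members_list, function(m) sort(as.character(m)))
  first <- vapply(members_list, function(m) if (length(m)) m[1L] else "",
                  character(1L))
  ord <- order(-lengths(members_list), first)
  members_list[ord]
}

#' Write a clustering to a cluster file
#'
#' One cluster per line, members tab-separated (MCL output dialect). Members
#' are sorted lexicographically and clusters by descending size then first
#' member, so output is bit-reproducible. Empty clusters are skipped with a
#' warning.
#'
#' @param clusters A clustering: tibble with `cluster`/`protein` columns, a
#'   list of protein-ID vectors, or a [ga_cluster()] fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  members <- clusters_as_list(clusters)
  if (!length(members)) stop("empty clustering")
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning(sprintf("skipped %d empty cluster(s)", sum(empty)))
    members <- members[!empty]
  }
  members <- order_clusters(members)
  writeLines(vapply(members, paste, character(1L), collapse = "\t"), path)
  invisible(path)
}

#' Read a cluster file
#'
#' Reads the one-cluster-per-line, tab/whitespace-separated dialect written by
#' [write_clusters()] (and by MCL), so externally produced clusterings can be
#' scored with [evaluate_clusters()].
#'
#' @param path Path to the cluster file.
#' @return A tibble with columns `cluster` (C1, C2, ... in file order) and
#'   `protein`.
#' @export
read_clusters <- function(path) {
  parsed <- read_noncomment_lines(path)
  lines <- parsed$lines[nzchar(trimws(parsed$lines))]
  if (!length(lines)) stop("empty cluster file: ", path)
  members <- strsplit(trimws(lines), "\\s+")
  clusters_as_tibble(lapply(members, unique))
}
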