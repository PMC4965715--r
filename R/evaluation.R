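#' Hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` marked proteins when `n` are drawn
#' without replacement from a universe of `N` proteins of which `M` are
#' marked (members of the reference complex):
#' \deqn{p = 1 - \sum_{i=0}^{k-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}.}
#' Computed through the numerically stable log-space tail of
#' [stats::phyper()]. `k = 0` gives exactly 1.
#'
#' @param n_universe `N`, number of proteins in the network.
#' @param n_marked `M`, complex members present in the network.
#' @param n_drawn `n`, size of the predicted cluster.
#' @param n_shared `k`, proteins shared between cluster and complex.
#' @return A p-value in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(n_universe, n_marked, n_drawn, n_shared) {
  N <- as.numeric(n_universe)
  M <- as.numeric(n_marked)
  n <- as.numeric(n_drawn)
  k <- as.numeric(n_shared)
  bad <- N < 0 | M < 0 | n < 0 | k < 0 | M > N | n > N | k > n | k > M
  if (any(bad)) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(M, n), M <= N, n <= N")
  }
  # upper tail P(X >= k) = P(X > k - 1)
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Precision, recall and F-measure of a cluster against a complex
#'
#' With `TP = C intersect G` (proteins shared by the predicted cluster `C`
#' and the reference complex `G`), `FP = C \ G`, and `TN = G \ C`:
#' `P = |TP| / |C|`, `R = |TP| / |G|`, and the F-measure is their harmonic
#' mean (0 when both are 0).
#'
#' @param cluster Character vector of cluster member protein IDs.
#' @param complex Character vector of reference complex member IDs.
#' @return A one-row tibble with `overlap`, `precision`, `recall`,
#'   `f_measure`.
#' @export
cluster_metrics <- function(cluster, complex) {
  cluster <- unique(as.character(cluster))
  complex <- unique(as.character(complex))
  if (!length(cluster) || !length(complex)) {
    stop("cluster and complex must be non-empty")
  }
  tp <- length(intersect(cluster, complex))
  p <- tp / length(cluster)
  r <- tp / length(complex)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(overlap = tp, precision = p, recall = r, f_measure = f)
}

#' Score predicted complexes against a reference catalog
#'
#' Every predicted cluster is matched to the reference complex minimizing
#' the hypergeometric p-value of their overlap (`N` = network proteins,
#' `M` = complex members in the network, `n` = cluster size, `k` = overlap;
#' ties break toward larger overlap, then lexicographic complex name).
#' Best-match p-values are Benjamini-Hochberg corrected across clusters by
#' default; clusters whose corrected p-value is at most `alpha` form the
#' significant set. Aggregates:
#' \itemize{
#'   \item precision: mean best-match precision over significant clusters;
#'   \item recall: mean, over reference complexes with at least one network
#'     member, of the best recall any significant cluster achieves for them
#'     (0 for unmatched complexes);
#'   \item f_measure: harmonic mean of the two aggregates;
#'   \item discard_ratio: fraction of network proteins in no predicted
#'     cluster.
#' }
#'
#' @param clusters Predicted clustering: tibble (`cluster`, `protein`), list
#'   of protein-ID vectors, or a [ga_cluster()] fit.
#' @param reference Reference catalog tibble (`complex`, `protein`), as from
#'   [read_reference_complexes()], or a named list of protein-ID vectors.
#' @param net The PPI network the clusters were predicted on.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Apply Benjamini-Hochberg correction across clusters'
#'   best-match p-values (default `TRUE`).
#' @return A `complex_evaluation` object with `matches` (per-cluster
#'   best-match records) and `summary` (one-row aggregate tibble). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
evaluate_clusters <- function(clusters, reference, net, alpha = 0.05,
                              p_adjust = TRUE) {
  net <- as_ppi_network(net)
  members <- lapply(clusters_as_list(clusters), function(m) unique(as.character(m)))
  members <- members[lengths(members) > 0L]
  if (!length(members)) stop("predicted clustering is empty")
  nm <- names(members)
  if (is.null(nm) || !all(nzchar(nm))) nm <- paste0("C", seq_along(members))

  ref <- reference_as_list(reference)
  # restrict complexes to the network universe: absent proteins cannot be
  # drawn from the network, so they leave the urn
  ref_net <- lapply(ref, function(g) intersect(g, net$proteins))
  in_net <- lengths(ref_net) > 0L
  if (!any(in_net)) {
    stop("no reference complex shares any protein with the network; ",
         "check that catalog and network use the same identifiers")
  }
  ref_net <- ref_net[in_net]
  ref_names <- sort(names(ref_net))
  ref_net <- ref_net[ref_names]

  N <- net$n
  best <- lapply(seq_along(members), function(ci) {
    cl <- members[[ci]]
    n <- length(cl)
    ov <- vapply(ref_net, function(g) length(intersect(cl, g)), integer(1L))
    hit <- which(ov >= 1L)
    if (!length(hit)) return(NULL)
    pv <- vapply(hit, function(gi) {
      hypergeom_pvalue(N, length(ref_net[[gi]]), n, ov[gi])
    }, numeric(1L))
    # min p; ties -> larger overlap -> lexicographic name (ref_names sorted)
    o <- order(pv, -ov[hit])
    gi <- hit[o[1L]]
    met <- cluster_metrics(cl, ref_net[[gi]])
    tibble::tibble(cluster = nm[ci], complex = ref_names[gi],
                   cluster_size = n, complex_size = length(ref_net[[gi]]),
                   overlap = met$overlap, p_value = pv[o[1L]],
                   precision = met$precision, recall = met$recall,
                   f_measure = met$f_measure)
  })
  matches <- dplyr::bind_rows(best)

  if (nrow(matches)) {
    matches$p_adjusted <- if (p_adjust) {
      stats::p.adjust(matches$p_value, method = "BH")
    } else {
      matches$p_value
    }
    matches$significant <- matches$p_adjusted <= alpha
  } else {
    matches <- tibble::tibble(cluster = character(), complex = character(),
                              cluster_size = integer(), complex_size = integer(),
                              overlap = integer(), p_value = numeric(),
                              precision = numeric(), recall = numeric(),
                              f_measure = numeric(), p_adjusted = numeric(),
                              significant = logical())
  }

  sig <- matches[matches$significant, , drop = FALSE]
  agg_p <- if (nrow(sig)) mean(sig$precision) else 0
  sig_members <- members[match(sig$cluster, nm)]
  complex_recall <- vapply(ref_net, function(g) {
    if (!length(sig_members)) return(0)
    max(vapply(sig_members, function(cl) length(intersect(cl, g)) / length(g),
               numeric(1L)))
  }, numeric(1L))
  agg_r <- mean(complex_recall)
  agg_f <- if (agg_p + agg_r > 0) 2 * agg_p * agg_r / (agg_p + agg_r) else 0
  covered <- length(unique(unlist(members, use.names = FALSE)))
  summary <- tibble::tibble(
    n_clusters = length(members),
    n_significant = nrow(sig),
    recall = agg_r,
    precision = agg_p,
    f_measure = agg_f,
    discard_ratio = 1 - covered / N
  )
  structure(list(matches = matches, summary = summary,
                 alpha = alpha, p_adjust = p_adjust),
            class = "complex_evaluation")
}

reference_as_list <- function(reference) {
  if (is.data.frame(reference)) {
    if (!all(c("complex", "protein") %in% names(reference))) {
      stop("reference tibble needs columns `complex` and `protein`")
    }
    ref <- split(as.character(reference$protein), reference$complex)
  } else if (is.list(reference)) {
    ref <- reference
  } else {
    stop("cannot interpret `reference` as a complex catalog")
  }
  if (is.null(names(ref)) || !all(nzchar(names(ref)))) {
    stop("reference complexes must be named")
  }
  lapply(ref, function(g) unique(as.character(g)))
}

#' @export
print.complex_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<complex_evaluation> %d clusters, %d significant ",
                     "(alpha = %g%s)\n"),
              s$n_clusters, s$n_significant, x$alpha,
              if (x$p_adjust) ", BH-corrected" else ""))
  cat(sprintf("  recall %.3f  precision %.3f  F %.3f  discard %.1f%%\n",
              s$recall, s$precision, s$f_measure, 100 * s$discard_ratio))
  invisible(x)
}

#' Compare clustering methods in one table
#'
#' Binds the aggregate rows of several [evaluate_clusters()] reports into a
#' comparison table (one row per method: cluster count, recall, precision,
#' F-measure, discard ratio), in the order given. To compare against several
#' reference catalogs, pass a named list of evaluations per method; the
#' per-catalog columns are suffixed with the catalog name.
#'
#' @param reports A named list: each element either a `complex_evaluation`
#'   or a named list of them keyed by reference catalog.
#' @return A tibble with one row per method.
#' @export
compare_methods <- function(reports) {
  if (!length(reports)) stop("need at least one report")
  if (is.null(names(reports)) || !all(nzchar(names(reports)))) {
    stop("reports must be named by method")
  }
  rows <- lapply(names(reports), function(meth) {
    rep_ <- reports[[meth]]
    if (inherits(rep_, "complex_evaluation")) {
      dplyr::bind_cols(tibble::tibble(method = meth),
                       rep_$summary[c("n_clusters", "recall", "precision",
                                      "f_measure", "discard_ratio")])
    } else {
      refs <- names(rep_)
      base <- tibble::tibble(
        method = meth,
        n_clusters = rep_[[1L]]$summary$n_clusters,
        discard_ratio = rep_[[1L]]$summary$discard_ratio
      )
      for (r in refs) {
        s <- rep_[[r]]$summary
        base[[paste0("recall_", r)]] <- s$recall
        base[[paste0("precision_", r)]] <- s$precision
        base[[paste0("f_measure_", r)]] <- s$f_measure
      }
      base
    }
  })
  dplyr::bind_rows(rows)
}
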