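#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GA fit
#'
#' `tidy()` returns one row per predicted complex (id, size, its
#' density-fitness ingredients are recoverable via [cluster_stats()]);
#' `glance()` returns a one-row model summary.
#'
#' @param x A [ga_cluster()] fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ga_fit <- function(x, ...) {
  if (!nrow(x$clusters)) {
    return(tibble::tibble(cluster = character(), size = integer(),
                          proteins = list()))
  }
  members <- clusters_as_list(x$clusters)
  tibble::tibble(
    cluster = names(members),
    size = lengths(members),
    proteins = unname(members)
  )
}

#' @rdname tidy.ga_fit
#' @export
glance.ga_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    init = x$init,
    best_fitness = x$best_fitness,
    generations_run = nrow(x$trace),
    n_complexes = length(unique(x$clusters$cluster)),
    discard_ratio = 1 - length(unique(x$clusters$protein)) / x$n_proteins
  )
}

#' Plot the GA fitness trace
#'
#' Best and mean population fitness per generation; the best trace is
#' monotone non-decreasing because of elitism.
#'
#' @param object A [ga_cluster()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_fit <- function(object, ...) {
  tr <- tidyr_longer_trace(object$trace)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = paste0("Fitness (", object$objective, ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# small manual pivot so tidyr is not a hard dependency
tidyr_longer_trace <- function(trace) {
  tibble::tibble(
    generation = rep(trace$generation, 2L),
    series = rep(c("best", "mean"), each = nrow(trace)),
    fitness = c(trace$best_fitness, trace$mean_fitness)
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-cluster best-match records (complex, overlap,
#' p-value, precision/recall/F); `glance()` the one-row aggregate summary.
#'
#' @param x A [evaluate_clusters()] report.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.complex_evaluation <- function(x, ...) x$matches

#' @rdname tidy.complex_evaluation
#' @export
glance.complex_evaluation <- function(x, ...) x$summary

#' Plot an evaluation report
#'
#' Best-match precision versus recall per predicted cluster, sized by
#' overlap and coloured by significance.
#'
#' @param object A [evaluate_clusters()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.complex_evaluation <- function(object, ...) {
  m <- object$matches
  ggplot2::ggplot(m, ggplot2::aes(x = .data$recall, y = .data$precision,
                                  size = .data$overlap,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", size = "Overlap",
                  colour = "Significant") +
    ggplot2::theme_minimal()
}
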