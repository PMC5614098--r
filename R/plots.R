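#' Plot cluster size distribution
#'
#' Histogram of cluster sizes on a log-scaled count axis, the standard
#' first look at a clustering's granularity.
#'
#' @param clustering A `miniclust_clustering`.
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(clustering) {
  sizes <- tidy(clustering)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "cluster size", y = "clusters") +
    ggplot2::theme_minimal()
}

#' Plot consistency reports
#'
#' Database-level worst and mean annotation consistency per annotation
#' type, mirroring the usual presentation of cluster-quality comparisons.
#' `plot_consistency()` accepts a single report or a named list of reports
#' (e.g. one per clustering level); `autoplot()` on a report delegates to
#' it.
#'
#' @param object A `consistency_report` or a named list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_consistency <- function(object, ...) {
  reports <- if (inherits(object, "consistency_report")) list(report = object)
             else object
  long <- dplyr::bind_rows(lapply(names(reports), function(nm) {
    g <- glance(reports[[nm]])
    tidyr::pivot_longer(
      g[, c("go_worst", "go_mean", "keyword_worst", "keyword_mean",
            "name_worst", "name_mean")],
      cols = dplyr::everything(),
      names_to = c("type", "stat"), names_sep = "_",
      values_to = "score") |>
      dplyr::mutate(level = nm)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$score,
                                     colour = .data$stat,
                                     group = .data$stat)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~type) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "annotation consistency") +
    ggplot2::theme_minimal()
}

#' @rdname plot_consistency
#' @export
autoplot.consistency_report <- function(object, ...) {
  plot_consistency(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
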