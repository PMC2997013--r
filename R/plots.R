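# ggplot2 displays for the main result types.

#' Plot a sliding-window diversity profile
#'
#' Bars of per-window pi along the consensus, coloured by the
#' conserved/intermediate/variable call, with the mean and the
#' mean +/- 2 SD thresholds drawn as horizontal lines.
#'
#' @param profile a `mite_diversity`.
#' @return a ggplot.
#' @export
plot_diversity_profile <- function(profile) {
  win <- profile$windows
  ggplot2::ggplot(win, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$pi, fill = .data$class)) +
    ggplot2::geom_col(width = (win$end - win$start)[1] * 0.9) +
    ggplot2::geom_hline(yintercept = profile$mean_pi, linetype = 2) +
    ggplot2::geom_hline(yintercept = profile$mean_pi + 2 * profile$sd_pi,
                        linetype = 3) +
    ggplot2::geom_hline(yintercept = max(0, profile$mean_pi -
                                           2 * profile$sd_pi),
                        linetype = 3) +
    ggplot2::scale_fill_manual(values = c(conserved = "#2166ac",
                                          intermediate = "grey60",
                                          variable = "#b2182b")) +
    ggplot2::labs(x = "consensus position (bp)",
                  y = "nucleotide diversity (pi)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of per-copy insertion ages
#'
#' @param ages tibble from [family_ages()] (optionally several families
#'   bound together with a `family_id` column).
#' @param binwidth bin width in million years.
#' @return a ggplot.
#' @export
plot_insertion_ages <- function(ages, binwidth = 0.25) {
  p <- ggplot2::ggplot(ages[!is.na(ages$t_my), ],
                       ggplot2::aes(x = .data$t_my)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "insertion age (My)", y = "copies") +
    ggplot2::theme_minimal()
  if ("family_id" %in% names(ages)) {
    p <- p + ggplot2::facet_wrap(~family_id, scales = "free_y")
  }
  p
}

#' Plot a haplotype network
#'
#' Simple force-free layout: nodes on a circle (igraph layout when
#' available), area proportional to multiplicity, median vectors as open
#' points.
#'
#' @param x a `mite_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mite_network <- function(x, ...) {
  n <- nrow(x$nodes)
  if (requireNamespace("igraph", quietly = TRUE) && nrow(x$edges) > 0) {
    g <- as_igraph(x)
    xy <- igraph::layout_with_fr(g)
  } else {
    theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    xy <- cbind(cos(theta), sin(theta))
  }
  nodes <- dplyr::mutate(x$nodes, x = xy[, 1], y = xy[, 2])
  edges <- dplyr::mutate(x$edges,
                         x = nodes$x[.data$from], y = nodes$y[.data$from],
                         xend = nodes$x[.data$to], yend = nodes$y[.data$to])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = pmax(.data$multiplicity, 0.5),
                                     shape = .data$is_median),
                        colour = "#2166ac") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::guides(shape = "none") +
    ggplot2::labs(size = "copies") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed vs null insertion-category fractions
#'
#' @param contexts observed contexts from [classify_insertions()].
#' @param null a `mite_null_sim`.
#' @return a ggplot.
#' @export
plot_insertion_categories <- function(contexts, null) {
  obs <- table(contexts$category) / nrow(contexts)
  df <- dplyr::bind_rows(
    tibble(category = names(obs), fraction = as.numeric(obs),
           set = "observed"),
    dplyr::mutate(tidy.mite_null_sim(null), set = "null"))
  df$category <- factor(df$category, levels = CATEGORY_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of insertions", fill = NULL) +
    ggplot2::theme_minimal()
}
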