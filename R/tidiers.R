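#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a chi-square result
#'
#' @param x a `mitescan_chisq`.
#' @param ... unused.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
tidy.mitescan_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = x$method)
}

#' @rdname tidy.mitescan_chisq
#' @export
glance.mitescan_chisq <- function(x, ...) tidy.mitescan_chisq(x)

#' Tidy a haplotype network (edge list)
#'
#' @param x a `mite_network`.
#' @param ... unused.
#' @return edges tibble with endpoint haplotypes and multiplicities.
#' @export
tidy.mite_network <- function(x, ...) {
  ed <- x$edges
  ed$from_haplotype <- x$nodes$haplotype[ed$from]
  ed$to_haplotype <- x$nodes$haplotype[ed$to]
  ed
}

#' One-row summary of a haplotype network
#'
#' @param x a `mite_network`.
#' @param ... unused.
#' @return tibble: node/edge counts, median-vector count, sequence count,
#'   and the star-topology statistic.
#' @export
glance.mite_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_median = sum(x$nodes$is_median),
         n_sequences = sum(x$nodes$multiplicity),
         star_statistic = star_statistic(x))
}

#' Tidy a diversity profile (per-window rows)
#'
#' @param x a `mite_diversity`.
#' @param ... unused.
#' @return the windows tibble.
#' @export
tidy.mite_diversity <- function(x, ...) x$windows

#' One-row summary of a diversity profile
#'
#' @param x a `mite_diversity`.
#' @param ... unused.
#' @export
glance.mite_diversity <- function(x, ...) {
  tibble(n_windows = nrow(x$windows), mean_pi = x$mean_pi, sd_pi = x$sd_pi,
         n_variable = sum(x$windows$class == "variable"),
         n_conserved = sum(x$windows$class == "conserved"))
}

#' Tidy a null-simulation result
#'
#' @param x a `mite_null_sim`.
#' @param ... unused.
#' @return tibble of category fractions.
#' @export
tidy.mite_null_sim <- function(x, ...) {
  tibble(category = names(x$category_fractions),
         fraction = unname(x$category_fractions))
}

#' @rdname tidy.mite_null_sim
#' @export
glance.mite_null_sim <- function(x, ...) {
  tibble(n = x$n, seed = x$seed, in_gene_fraction = x$in_gene_fraction)
}
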