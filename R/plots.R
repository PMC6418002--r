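# Plot and tidier methods for the package's result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a protein cluster set
#'
#' One row per cluster with its size and per-strain presence count.
#' @param x a `protein_cluster_set`.
#' @param ... unused.
#' @return tibble `cluster`, `n_members`, `n_strains`, `is_core`.
#' @export
tidy.protein_cluster_set <- function(x, ...) {
  x$members |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_members = dplyr::n(),
                     n_strains = dplyr::n_distinct(.data$strain),
                     .groups = "drop") |>
    dplyr::mutate(is_core = .data$n_strains == ncol(x$presence))
}

#' One-line summary of a protein cluster set
#' @param x a `protein_cluster_set`.
#' @param ... unused.
#' @return one-row tibble `n_clusters`, `n_strains`, `n_core`, `n_proteins`.
#' @export
glance.protein_cluster_set <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$presence),
                 n_strains = ncol(x$presence),
                 n_core = sum(rowSums(x$presence) == ncol(x$presence)),
                 n_proteins = nrow(x$members))
}

#' Accumulation boxplot (pan and core genome vs genomes sampled)
#'
#' @param object an `accumulation_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("pan", "core"), names_to = "set",
                        values_to = "clusters")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$g), y = .data$clusters,
                                     fill = .data$set)) +
    ggplot2::geom_boxplot(coef = Inf, position = "dodge") +
    ggplot2::labs(x = "genomes sampled", y = "protein clusters",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of mean dN/dS per creation node
#'
#' @param object a `node_omega_summary` from [aggregate_by_node()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.node_omega_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$mean_omega)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_omega - .data$sd_omega),
      ymax = .data$mean_omega + .data$sd_omega), width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "creation/acquisition node", y = "mean dN/dS") +
    ggplot2::theme_minimal()
}

#' Dotplot of matched segments between two genomes
#'
#' @param object a `dotplot_matches` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dotplot_matches <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$yend <- ifelse(d$orientation == "direct", d$end_b, d$start_b)
  d$y <- ifelse(d$orientation == "direct", d$start_b, d$end_b)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_a, xend = .data$end_a,
                                       y = .data$y, yend = .data$yend,
                                       colour = .data$orientation)) +
    ggplot2::labs(x = "genome A (bp)", y = "genome B (bp)", colour = NULL) +
    ggplot2::theme_minimal()
}
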