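#' Plot an MDS embedding of gene trees
#'
#' Scatter of the gene-tree cloud in the first two MDS axes, with the
#' species tree marked, the usual visual summary of genome-wide topological
#' conflict.
#'
#' @param x Output of [rf_mds()] (a tibble with `MDS1`, `MDS2`,
#'   `is_species_tree`) or a `"phylo_mds"` object.
#' @return A ggplot object.
#' @export
plot_mds <- function(x) {
  if (inherits(x, "phylo_mds")) {
    x <- dplyr::mutate(x$points, is_species_tree = FALSE)
  }
  stopifnot(all(c("MDS1", "MDS2") %in% names(x)))
  ggplot2::ggplot(x, ggplot2::aes(.data$MDS1, .data$MDS2)) +
    ggplot2::geom_point(data = dplyr::filter(x, !.data$is_species_tree),
                        colour = "steelblue", alpha = 0.6, size = 1.5) +
    ggplot2::geom_point(data = dplyr::filter(x, .data$is_species_tree),
                        colour = "red", shape = 17, size = 3) +
    ggplot2::labs(x = "MDS1", y = "MDS2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phylo_mds <- function(object, ...) plot_mds(object)

#' Plot quartet proportions on the topology simplex
#'
#' Each quartet is a point inside the equilateral reference triangle whose
#' vertices are the three possible sister-pair topologies; position is the
#' mix of observed topology counts, colour/shape the MSC-test verdict.
#' Points near the centroid are heavily ILS-affected.
#'
#' @param quartets Output of [quartet_analysis()].
#' @return A ggplot object.
#' @export
plot_quartet_simplex <- function(quartets) {
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  pts <- dplyr::filter(quartets, !is.na(.data$x))
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = tri, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$verdict,
                                     shape = .data$verdict),
                        alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(ILS_consistent = "steelblue",
                                            rejected = "firebrick",
                                            undetermined = "grey60")) +
    ggplot2::scale_shape_manual(values = c(ILS_consistent = 16,
                                           rejected = 17,
                                           undetermined = 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot branch-length distributions by topology class
#'
#' Box plots of a per-gene statistic (divergence branch length or cumulative
#' length) across topology classes.
#'
#' @param records Output of [classify_gene_trees()].
#' @param value Column to plot (string), default
#'   `"divergence_branch_length"`.
#' @return A ggplot object.
#' @export
plot_branch_lengths <- function(records, value = "divergence_branch_length") {
  stopifnot(value %in% names(records))
  dat <- dplyr::filter(records, !is.na(.data$class),
                       !is.na(.data[[value]]))
  ggplot2::ggplot(dat, ggplot2::aes(.data$class, .data[[value]],
                                    fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
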