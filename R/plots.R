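# ggplot2 visualizations for the main result types. Tables are the
# pipeline contract; these plots are the standard views of them.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential result
#'
#' @param object A [test_peptides()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pep_diff
#' @export
autoplot.pep_diff <- function(object, ...) {
  v <- volcano_table(object)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey70")) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "p_threshold")),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(attr(object, "fc_threshold")),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sample score plot of a peptide PCA
#'
#' @param object A [peptide_pca()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pep_pca
#' @export
autoplot.pep_pca <- function(object, ...) {
  evr <- object$explained_variance_ratio
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * evr[2])) +
    ggplot2::theme_minimal()
}

#' Helical-wheel plot
#'
#' @param object A [wheel_projection()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pep_wheel
#' @export
autoplot.pep_wheel <- function(object, ...) {
  d <- tibble::as_tibble(object)
  # spiral radius separates residues landing on the same spoke
  d$radius <- 1 + 0.05 * (d$index - 1)
  d$x <- d$radius * cos(d$angle_deg * pi / 180)
  d$y <- d$radius * sin(d$angle_deg * pi / 180)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$residue_class), size = 7,
                        shape = 21) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$residue,
                                                   .data$index)), size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = NULL, x = NULL, y = NULL,
                  title = attr(object, "sequence")) +
    ggplot2::theme_void()
}

#' Cleavage-profile bar chart
#'
#' @param object A [cleavage_profile()] result.
#' @param ... Unused.
#' @return A ggplot faceted by direction stratum and cleavage position.
#' @method autoplot pep_cleavage
#' @export
autoplot.pep_cleavage <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$residue, y = .data$n)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$direction),
                        cols = ggplot2::vars(.data$position)) +
    ggplot2::labs(x = "residue", y = "count") +
    ggplot2::theme_minimal()
}

#' Peptide alignment (coverage) map
#'
#' Per-residue peptide coverage of one precursor, split by differential
#' direction.
#'
#' @param coverage A [coverage_map()] result.
#' @return A ggplot.
#' @export
plot_coverage_map <- function(coverage) {
  long <- tidyr::pivot_longer(coverage, c("n_up", "n_down", "n_all"),
                              names_to = "stratum", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$n,
                                     fill = .data$stratum)) +
    ggplot2::geom_area(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "precursor position", y = "peptides covering",
                  title = coverage$precursor_acc[1]) +
    ggplot2::theme_minimal()
}
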