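# ggplot2 visualisations for the main result types. All plot functions
# return ggplot objects so callers can restyle them.

#' Plot domain architectures of family members
#'
#' Draws each protein as a horizontal line with its zinc-finger domains
#' as colored boxes (Q-type vs M-type).
#'
#' @param domains Domain-hit tibble from [scan_zf_domains()].
#' @param protein_lengths Optional named vector of protein lengths (for
#'   the backbone line); defaults to each protein's last domain end.
#' @return A ggplot object.
#' @export
plot_domain_architecture <- function(domains, protein_lengths = NULL) {
  ids <- unique(domains$protein_id)
  lens <- protein_lengths %||%
    setNames(vapply(ids, function(i)
      max(domains$end[domains$protein_id == i]), numeric(1)), ids)
  backbone <- tibble(protein_id = ids, length = unname(lens[ids]))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = 1, xend = .data$length, y = .data$protein_id,
                   yend = .data$protein_id),
      linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = as.numeric(factor(.data$protein_id, ids)) - 0.3,
                   ymax = as.numeric(factor(.data$protein_id, ids)) + 0.3,
                   fill = .data$zf_class)) +
    ggplot2::scale_fill_manual(values = c(Q = "#2166ac", M = "#b2182b")) +
    ggplot2::labs(x = "residue", y = NULL, fill = "finger type") +
    ggplot2::theme_minimal()
}

#' Bar chart of members per chromosome
#'
#' @param distribution Tibble from [chromosome_distribution()].
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(distribution) {
  distribution$chromosome <- factor(distribution$chromosome,
                                    levels = distribution$chromosome)
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$chromosome, y = .data$n)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = NULL, y = "family members") +
    ggplot2::theme_minimal()
}

#' Bar chart of cis-element category counts
#'
#' @param cis_summary List from [summarize_categories()].
#' @return A ggplot object.
#' @export
plot_cis_categories <- function(cis_summary) {
  ggplot2::ggplot(cis_summary$categories,
                  ggplot2::aes(x = stats::reorder(.data$category, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "#5aae61") +
    ggplot2::labs(x = NULL, y = "cis-element hits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Expression heatmap (log2(FPKM + 1)) for an expression matrix
#'
#' @param object A `qzfp_expr` from [expression_matrix()].
#' @param ... Unused.
#' @return A ggplot tile heatmap of log2(FPKM + 1) values.
#' @export
autoplot.qzfp_expr <- function(object, ...) {
  lg <- log_fpkm(fpkm(object))
  long <- tidyr::pivot_longer(lg, -"gene_id", names_to = "sample",
                              values_to = "log2_fpkm1")
  long$sample <- factor(long$sample, levels = object$samples$sample_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$log2_fpkm1)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(FPKM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
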