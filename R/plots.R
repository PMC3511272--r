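#' Plot TE density around LGT and other genes
#'
#' Mean number of transposable elements (with standard-error bars) in each
#' flanking-window size, by gene class — the shape of the study's TE-density
#' figure.
#'
#' @param te_report Tibble from `te_density_report()`.
#' @return A ggplot object.
#' @export
plot_te_density <- function(te_report) {
  ggplot2::ggplot(te_report,
                  ggplot2::aes(x = factor(.data$window), y = .data$mean,
                               colour = .data$class, group = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::labs(x = "flanking window size (bp)",
                  y = "mean TEs per gene (flanks)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_te_density
#' @param object An `lgt_te_test`.
#' @param ... Unused.
#' @export
autoplot.lgt_te_test <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$class, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean TEs per gene (flanks)") +
    ggplot2::theme_minimal()
}

#' Plot donor-clade taxonomy summary
#'
#' Counts of trees with at least one (and with only) donor species of each
#' taxonomic division.
#'
#' @param donor_summary Tibble from `summarize_donor_taxa()`.
#' @return A ggplot object.
#' @export
plot_donor_summary <- function(donor_summary) {
  long <- donor_summary %>%
    select("division", "n_trees_any", "n_trees_only") %>%
    tidyr::pivot_longer(-"division", names_to = "mode", values_to = "n") %>%
    mutate(mode = ifelse(.data$mode == "n_trees_any",
                         "at least one", "only"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$division, y = .data$n,
                                     fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "trees", fill = "donor clade contains") +
    ggplot2::theme_minimal()
}

#' Plot a codon-usage comparison
#'
#' Per-codon usage fractions (within each amino-acid class) for the two gene
#' sets side by side.
#'
#' @param object A `codon_usage_comparison`.
#' @param ... Unused.
#' @export
autoplot.codon_usage_comparison <- function(object, ...) {
  long <- object$per_codon %>%
    select("codon", "amino_acid", "fraction_a", "fraction_b") %>%
    tidyr::pivot_longer(c("fraction_a", "fraction_b"),
                        names_to = "set", values_to = "fraction") %>%
    mutate(set = ifelse(.data$set == "fraction_a", "LGT", "Rest"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$fraction,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(~amino_acid, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "fraction within amino-acid class",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
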