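# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_boxplot
#'   geom_col geom_abline geom_vline labs theme_minimal
#' @export
ggplot2::autoplot

#' PCA view of samples coloured by tissue
#'
#' @param object A `circ_pca` tibble from [pca_samples()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot circ_pca
#' @export
autoplot.circ_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot(object, aes(x = .data$PC1, y = .data$PC2, colour = .data$tissue)) +
    geom_point(size = 2, alpha = 0.8) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
         colour = "tissue") +
    theme_minimal()
}

#' Overall circular fraction against age
#'
#' @param object A `circ_age_trend` from [overall_fraction_trend()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot circ_age_trend
#' @export
autoplot.circ_age_trend <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$age_weeks, y = .data$overall_fraction)) +
    geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "line", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    labs(title = sprintf("%s: rho = %.3f", object$tissue, object$rho),
         x = "age (weeks)", y = "overall circular fraction") +
    theme_minimal()
}

#' Circular fraction by expression bin
#'
#' @param x A `circ_fraction_bins` from [fraction_by_expression_bin()].
#' @return A ggplot (boxplot of fraction per expression bin).
#' @export
plot_fraction_bins <- function(x) {
  ggplot(x$per_gene, aes(x = factor(.data$bin), y = .data$fraction)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = "host-gene expression bin (low to high)",
         y = "circular fraction") +
    theme_minimal()
}

#' Paired circular versus linear TSI
#'
#' @param x A `circ_tsi_comparison` from [paired_tsi_comparison()].
#' @return A ggplot (per-gene scatter with the identity line).
#' @export
plot_tsi_comparison <- function(x) {
  ggplot(x$per_gene, aes(x = .data$tsi_linear, y = .data$tsi_circ)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "TSI (linear)", y = "TSI (circular)") +
    theme_minimal()
}

#' Bar chart of top enriched terms
#'
#' @param enrichments Tibble from [enrich_gene_sets()].
#' @param k Number of terms to show.
#' @param alpha Significance level drawn as a dashed line.
#' @return A ggplot of -log10 P for the top terms by Z-score.
#' @export
plot_top_terms <- function(enrichments, k = 10, alpha = 0.05) {
  top <- top_terms_report(enrichments, k)
  top$set_name <- factor(top$set_name, levels = rev(top$set_name))
  ggplot(top, aes(x = -log10(.data$p_value), y = .data$set_name)) +
    geom_col(fill = "indianred") +
    geom_vline(xintercept = -log10(alpha), linetype = 2) +
    labs(x = expression(-log[10](P)), y = NULL) +
    theme_minimal()
}
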