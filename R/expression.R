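#' Circular fraction of a host gene's output
#'
#' `TPM_circ / (TPM_circ + TPM_linear)`, the share of a host gene's
#' transcriptional output spliced into circles. Undefined (`NA`) when both
#' layers are 0; such genes are excluded from fraction-based analyses. The
#' statistic is invariant to rescaling both layers by a common factor.
#'
#' @param tpm_circ,tpm_linear Non-negative numeric vectors.
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' circular_fraction(2, 8)   # 0.2
#' circular_fraction(0, 0)   # NA
#' @export
circular_fraction <- function(tpm_circ, tpm_linear) {
  if (any(tpm_circ < 0, na.rm = TRUE) || any(tpm_linear < 0, na.rm = TRUE))
    abort("TPM values must be non-negative")
  total <- tpm_circ + tpm_linear
  ifelse(total > 0, tpm_circ / total, NA_real_)
}

#' Correlation between circular and linear expression in one tissue
#'
#' Per host gene, the circular and linear TPM are averaged over the
#' tissue's samples (pooling ages and sexes); Spearman's rank correlation
#' is then computed across genes expressed in the circular layer (mean
#' `TPM_circ > 0`). Also reports how many genes have higher mean circular
#' than linear expression.
#'
#' @param expression Paired-expression tibble (`gene_id`, `sample_id`,
#'   `tpm_circ`, `tpm_linear`).
#' @param metadata Sample metadata tibble.
#' @param tissue Tissue label present in the metadata.
#' @return A one-row tibble: `tissue`, `rho`, `p_value`, `n_genes`,
#'   `n_circ_higher`. `rho` is `NA` when undefined (constant layer).
#' @export
circ_linear_correlation <- function(expression, metadata, tissue) {
  assert_expression(expression); assert_metadata(metadata)
  means <- tissue_slice(expression, metadata, tissue) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_circ = mean(.data$tpm_circ),
                     mean_linear = mean(.data$tpm_linear), .groups = "drop") |>
    dplyr::filter(.data$mean_circ > 0)
  st <- spearman_test(means$mean_linear, means$mean_circ)
  tibble(tissue = tissue, rho = st$rho, p_value = st$p_value,
         n_genes = nrow(means),
         n_circ_higher = sum(means$mean_circ > means$mean_linear))
}

#' Circular fraction by host-gene expression bin
#'
#' Genes are binned into `n_bins` quantile bins of total mean expression
#' (`TPM_circ + TPM_linear`, averaged over the tissue's samples); the
#' distribution of the circular fraction is reported per bin, and the
#' association between total expression and circular fraction across genes
#' is tested with Spearman's rank correlation.
#'
#' @inheritParams circ_linear_correlation
#' @param n_bins Number of quantile bins (default 10); must not exceed the
#'   number of genes with defined fraction.
#' @return A list of class `circ_fraction_bins`: `per_gene` (gene_id,
#'   total_expression, fraction, bin), `per_bin` (bin, n, median_fraction,
#'   mean_fraction), `trend` (rho, p_value, n).
#' @export
fraction_by_expression_bin <- function(expression, metadata, tissue, n_bins = 10) {
  assert_expression(expression); assert_metadata(metadata)
  per_gene <- tissue_slice(expression, metadata, tissue) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_circ = mean(.data$tpm_circ),
                     mean_linear = mean(.data$tpm_linear), .groups = "drop") |>
    dplyr::mutate(total_expression = .data$mean_circ + .data$mean_linear,
                  fraction = circular_fraction(.data$mean_circ, .data$mean_linear)) |>
    dplyr::filter(!is.na(.data$fraction))
  if (n_bins < 1 || n_bins > nrow(per_gene))
    abort("n_bins must be between 1 and the number of genes with defined fraction")
  per_gene <- per_gene |>
    dplyr::mutate(bin = dplyr::ntile(.data$total_expression, n_bins)) |>
    dplyr::select("gene_id", "total_expression", "fraction", "bin")
  per_bin <- per_gene |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     median_fraction = median(.data$fraction),
                     mean_fraction = mean(.data$fraction), .groups = "drop")
  # an (up to rounding) constant fraction carries no trend: rho 0 by
  # convention
  st <- if (diff(range(per_gene$fraction)) <= 1e-12)
    list(rho = 0, p_value = 1, n = nrow(per_gene))
  else spearman_test(per_gene$total_expression, per_gene$fraction)
  structure(list(per_gene = per_gene, per_bin = per_bin,
                 trend = tibble(rho = st$rho, p_value = st$p_value, n = st$n)),
            class = "circ_fraction_bins")
}

#' @export
print.circ_fraction_bins <- function(x, ...) {
  cat("<circ_fraction_bins>\n")
  print(x$per_bin, n = Inf)
  cat(sprintf(" trend: rho = %.3f, P = %.3g (n = %d genes)\n",
              x$trend$rho, x$trend$p_value, x$trend$n))
  invisible(x)
}

#' Per-sample counts of highly expressed circRNA host genes
#'
#' Counts, per sample, the host genes whose `TPM_circ` falls strictly
#' between the two thresholds and strictly above the upper one (the
#' `50 < TPM < 100` and `TPM > 100` bands by default).
#'
#' @param expression Paired-expression tibble.
#' @param metadata Sample metadata tibble.
#' @param thresholds Increasing numeric pair `(lower, upper)`.
#' @return Tibble `sample_id`, `tissue`, `n_mid` (lower < TPM < upper),
#'   `n_high` (TPM > upper).
#' @export
high_expression_counts <- function(expression, metadata, thresholds = c(50, 100)) {
  assert_expression(expression); assert_metadata(metadata)
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    abort("thresholds must be an increasing pair")
  expression |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_mid = sum(.data$tpm_circ > thresholds[1] & .data$tpm_circ < thresholds[2]),
      n_high = sum(.data$tpm_circ > thresholds[2]), .groups = "drop") |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "tissue"),
                     by = "sample_id") |>
    dplyr::relocate("tissue", .after = "sample_id")
}

#' Paired comparison of circular versus linear expression
#'
#' Paired t-test of `log2(TPM + 1)` between the circular and linear layers
#' across all gene/sample pairs, the overall check that circRNA abundance
#' sits below the cognate mRNA abundance when the circular fraction is
#' below one half.
#'
#' @param expression Paired-expression tibble.
#' @param alternative Alternative hypothesis for the circular minus linear
#'   difference (default `"less"`).
#' @return One-row tibble: `statistic`, `p_value`, `mean_difference`, `n`.
#' @export
paired_expression_test <- function(expression, alternative = "less") {
  assert_expression(expression)
  a <- log2(expression$tpm_circ + 1)
  b <- log2(expression$tpm_linear + 1)
  tt <- t.test(a, b, paired = TRUE, alternative = alternative)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         mean_difference = unname(tt$estimate), n = length(a))
}
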