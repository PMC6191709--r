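#' Tissue specificity index (tau)
#'
#' `TSI = sum(1 - r_i) / (N - 1)` over `N` tissues, with `r_i` the mean
#' expression in tissue `i` normalised to the maximum tissue mean. 0 means
#' uniform expression, 1 means expression confined to a single tissue. The
#' index is invariant to positive rescaling and undefined (`NA`) for an
#' all-zero vector.
#'
#' @param mean_expr_by_tissue Non-negative numeric vector of per-tissue
#'   mean expression, length >= 2.
#' @return A value in `[0, 1]`, or `NA` for an all-zero vector.
#' @examples
#' tsi(c(10, 0, 0, 0))  # 1
#' tsi(c(5, 5, 5))      # 0
#' tsi(c(10, 5, 0))     # 0.75
#' @export
tsi <- function(mean_expr_by_tissue) {
  x <- mean_expr_by_tissue
  if (length(x) < 2L) abort("TSI needs at least 2 tissues")
  if (any(!is.finite(x)) || any(x < 0)) abort("TSI input must be finite and non-negative")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1L)
}

# per-gene per-tissue means of both layers (+ fraction layer)
tissue_mean_table <- function(expression, metadata) {
  expression |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "tissue"),
                     by = "sample_id") |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(mean_circ = mean(.data$tpm_circ),
                     mean_linear = mean(.data$tpm_linear),
                     mean_fraction = mean(circular_fraction(.data$tpm_circ,
                                                            .data$tpm_linear),
                                          na.rm = TRUE),
                     .groups = "drop")
}

#' Per-gene TSI of the circular, linear and fraction layers
#'
#' @param expression Paired-expression tibble.
#' @param metadata Sample metadata tibble.
#' @return Tibble `gene_id`, `tsi_circ`, `tsi_linear`, `tsi_fraction`,
#'   `argmax_tissue` (tissue of maximal mean circular expression),
#'   `peak_tpm_circ`. TSI columns are `NA` where the layer is all zero.
#' @export
tsi_table <- function(expression, metadata) {
  assert_expression(expression); assert_metadata(metadata)
  tm <- tissue_mean_table(expression, metadata)
  tm |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      tsi_circ = tsi(.data$mean_circ),
      tsi_linear = tsi(.data$mean_linear),
      tsi_fraction = tsi(ifelse(is.finite(.data$mean_fraction),
                                .data$mean_fraction, 0)),
      argmax_tissue = .data$tissue[which.max(.data$mean_circ)],
      peak_tpm_circ = max(.data$mean_circ),
      .groups = "drop")
}

#' Paired comparison of circular versus linear tissue specificity
#'
#' Computes per-gene TSI for both layers, a paired Wilcoxon signed-rank
#' test of circular minus linear TSI, the per-layer counts of genes with
#' TSI above a high-specificity cut (0.8), and the same TSI computed on
#' the circular-fraction layer. With fewer than 2 genes the test is
#' skipped with an explicit status.
#'
#' @inheritParams tsi_table
#' @param high_tsi High-specificity threshold used for the per-layer counts.
#' @return A list of class `circ_tsi_comparison`: `per_gene` (the
#'   [tsi_table()]), `test` (status, statistic, p_value, n),
#'   `high_counts` (layer, n_high).
#' @export
paired_tsi_comparison <- function(expression, metadata, high_tsi = 0.8) {
  per_gene <- tsi_table(expression, metadata)
  ok <- dplyr::filter(per_gene, !is.na(.data$tsi_circ), !is.na(.data$tsi_linear))
  test <- if (nrow(ok) < 2L) {
    tibble(status = "skipped: fewer than 2 genes", statistic = NA_real_,
           p_value = NA_real_, n = nrow(ok))
  } else if (all(ok$tsi_circ == ok$tsi_linear)) {
    tibble(status = "degenerate: all paired differences 0", statistic = 0,
           p_value = NA_real_, n = nrow(ok))
  } else {
    wt <- suppressWarnings(wilcox.test(ok$tsi_circ, ok$tsi_linear, paired = TRUE))
    tibble(status = "ok", statistic = unname(wt$statistic),
           p_value = wt$p.value, n = nrow(ok))
  }
  high_counts <- tibble(
    layer = c("circ", "linear"),
    n_high = c(sum(ok$tsi_circ > high_tsi), sum(ok$tsi_linear > high_tsi)))
  structure(list(per_gene = per_gene, test = test, high_counts = high_counts),
            class = "circ_tsi_comparison")
}

#' @export
print.circ_tsi_comparison <- function(x, ...) {
  cat("<circ_tsi_comparison> ", nrow(x$per_gene), "genes\n")
  print(x$test)
  print(x$high_counts)
  invisible(x)
}

#' Call tissue-specific circRNAs
#'
#' A gene's circRNA is called specific to its peak tissue (the tissue of
#' maximal mean circular expression) when its circular-layer TSI is at
#' least `tsi_threshold` and its peak mean `TPM_circ` is at least
#' `min_peak_tpm` (an expression floor that keeps near-zero genes from
#' being called on noise).
#'
#' @inheritParams tsi_table
#' @param tsi_threshold Minimum circular TSI (default 0.8).
#' @param min_peak_tpm Minimum peak mean `TPM_circ` (default 1).
#' @return Tibble `gene_id`, `tissue`, `tsi_circ`, `peak_tpm_circ` of the
#'   called genes.
#' @export
call_tissue_specific <- function(expression, metadata,
                                 tsi_threshold = 0.8, min_peak_tpm = 1.0) {
  tsi_table(expression, metadata) |>
    dplyr::filter(!is.na(.data$tsi_circ),
                  .data$tsi_circ >= tsi_threshold,
                  .data$peak_tpm_circ >= min_peak_tpm) |>
    dplyr::transmute(gene_id = .data$gene_id, tissue = .data$argmax_tissue,
                     tsi_circ = .data$tsi_circ,
                     peak_tpm_circ = .data$peak_tpm_circ)
}

#' Splicing-ratio contrast for tissue-specific circRNAs
#'
#' For each called circRNA, the mean circular fraction over samples of its
#' called tissue versus the mean over all other tissues' samples, with a
#' paired Wilcoxon signed-rank test of the in-tissue minus out-of-tissue
#' difference. Setting `layer = "linear"` applies the same contrast with
#' the linear fraction `1 - f`, the mirror analysis for tissue-specific
#' mRNAs.
#'
#' @inheritParams tsi_table
#' @param calls Call table from [call_tissue_specific()] (`gene_id`,
#'   `tissue`).
#' @param layer `"circ"` (default) or `"linear"`.
#' @return A list of class `circ_splicing_contrast`: `per_gene` (gene_id,
#'   tissue, in_fraction, out_fraction) and `test` (status, statistic,
#'   p_value, n).
#' @export
splicing_ratio_contrast <- function(expression, metadata, calls,
                                    layer = c("circ", "linear")) {
  layer <- match.arg(layer)
  assert_expression(expression); assert_metadata(metadata)
  df <- expression |>
    dplyr::inner_join(dplyr::select(calls, "gene_id", called_tissue = "tissue"),
                      by = "gene_id") |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "tissue"),
                     by = "sample_id") |>
    dplyr::mutate(fraction = circular_fraction(.data$tpm_circ, .data$tpm_linear),
                  fraction = if (layer == "linear") 1 - .data$fraction
                             else .data$fraction)
  per_gene <- df |>
    dplyr::group_by(.data$gene_id, .data$called_tissue) |>
    dplyr::summarise(
      in_fraction = mean(.data$fraction[.data$tissue == .data$called_tissue[1]],
                         na.rm = TRUE),
      out_fraction = mean(.data$fraction[.data$tissue != .data$called_tissue[1]],
                          na.rm = TRUE),
      .groups = "drop") |>
    dplyr::rename(tissue = "called_tissue")
  diffs <- per_gene$in_fraction - per_gene$out_fraction
  test <- if (nrow(per_gene) < 2L) {
    tibble(status = "skipped: fewer than 2 called genes", statistic = NA_real_,
           p_value = NA_real_, n = nrow(per_gene))
  } else if (all(diffs == 0)) {
    tibble(status = "degenerate: all paired differences 0", statistic = 0,
           p_value = NA_real_, n = nrow(per_gene))
  } else {
    wt <- suppressWarnings(wilcox.test(per_gene$in_fraction,
                                       per_gene$out_fraction, paired = TRUE))
    tibble(status = "ok", statistic = unname(wt$statistic),
           p_value = wt$p.value, n = nrow(per_gene))
  }
  structure(list(per_gene = per_gene, test = test),
            class = "circ_splicing_contrast")
}

#' @export
print.circ_splicing_contrast <- function(x, ...) {
  cat("<circ_splicing_contrast> ", nrow(x$per_gene), "called circRNAs\n")
  print(x$test)
  invisible(x)
}

#' PCA of circular expression across samples
#'
#' Principal component analysis of `log2(TPM_circ + 1)` (samples by genes,
#' centred, unscaled), returning the first two component coordinates per
#' sample. Coordinates are invariant to gene order, and duplicated samples
#' map to identical coordinates.
#'
#' @inheritParams tsi_table
#' @param genes Optional gene subset; default all genes.
#' @return A tibble of class `circ_pca`: `sample_id`, `tissue`,
#'   `age_weeks`, `PC1`, `PC2`; the fraction of variance explained is in
#'   `attr(, "var_explained")`.
#' @export
pca_samples <- function(expression, metadata, genes = NULL) {
  assert_expression(expression); assert_metadata(metadata)
  if (!is.null(genes))
    expression <- dplyr::filter(expression, .data$gene_id %in% genes)
  mat <- expression |>
    dplyr::select("gene_id", "sample_id", "tpm_circ") |>
    dplyr::mutate(value = log2(.data$tpm_circ + 1)) |>
    dplyr::arrange(.data$gene_id) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "gene_id",
                       values_from = "value")
  m <- as.matrix(mat[, -1, drop = FALSE])
  keep <- apply(m, 2L, function(v) stats::sd(v) > 0)
  pc <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  out <- tibble(sample_id = mat$sample_id,
                PC1 = pc$x[, 1],
                PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0) |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "tissue", "age_weeks"),
                     by = "sample_id") |>
    dplyr::relocate("tissue", "age_weeks", .after = "sample_id")
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  class(out) <- c("circ_pca", class(out))
  out
}

#' Hierarchical clustering of samples on tissue-specific circRNA expression
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance on
#' `log2(TPM_circ + 1)`) of samples restricted to the called
#' tissue-specific circRNAs, cut at one cluster per tissue, with a purity
#' report: the fraction of samples whose cluster's majority tissue is
#' their own tissue.
#'
#' @inheritParams tsi_table
#' @param calls Call table from [call_tissue_specific()]; its `gene_id`
#'   column restricts the expression matrix.
#' @return A list of class `circ_clustering`: `hclust` (the tree),
#'   `assignments` (sample_id, tissue, cluster), `purity`.
#' @export
cluster_samples <- function(expression, metadata, calls) {
  assert_expression(expression); assert_metadata(metadata)
  if (nrow(calls) == 0L) abort("no called tissue-specific circRNAs to cluster on")
  mat <- expression |>
    dplyr::filter(.data$gene_id %in% calls$gene_id) |>
    dplyr::mutate(value = log2(.data$tpm_circ + 1)) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "gene_id",
                       values_from = "value")
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- mat$sample_id
  hc <- hclust(dist(m), method = "ward.D2")
  k <- dplyr::n_distinct(metadata$tissue[metadata$sample_id %in% mat$sample_id])
  cl <- cutree(hc, k = k)
  assignments <- tibble(sample_id = names(cl), cluster = unname(cl)) |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "tissue"),
                     by = "sample_id")
  purity <- assignments |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(majority = names(which.max(table(.data$tissue)))) |>
    dplyr::ungroup() |>
    dplyr::summarise(p = mean(.data$tissue == .data$majority)) |>
    dplyr::pull("p")
  structure(list(hclust = hc, assignments = assignments, purity = purity),
            class = "circ_clustering")
}

#' @export
print.circ_clustering <- function(x, ...) {
  cat("<circ_clustering> ", nrow(x$assignments), "samples, purity",
      sprintf("%.3f", x$purity), "\n")
  invisible(x)
}
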