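#' Spearman rank correlation with midranks
#'
#' Spearman's rho computed as the Pearson correlation of midranks, the
#' convention used throughout the package for expression-versus-age and
#' expression-versus-expression associations. Ties (for example the four
#' replicate samples sharing one age) receive midranks, so the coefficient
#' with a tied regressor is bounded away from 1 even for a perfectly
#' age-ordered response.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single correlation in `[-1, 1]`, or `NA` when either vector is
#'   constant (the rank correlation is undefined).
#' @examples
#' spearman_rho(1:10, (1:10)^3) # 1: invariant to monotone transforms
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(rank(x), rank(y))
}

# Spearman test wrapper: rho via midranks, p via cor.test's asymptotic
# approximation (exact = FALSE so tied data do not warn).
spearman_test <- function(x, y) {
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_, n = sum(is.finite(x) & is.finite(y))))
  ok <- is.finite(x) & is.finite(y)
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

# Column-wise Spearman of each column of `m` against `x` (midrank Pearson),
# vectorised for the per-gene age correlations.
spearman_rho_cols <- function(x, m) {
  rx <- rank(x)
  rx <- (rx - mean(rx)) / stats::sd(rx)
  rm <- apply(m, 2L, rank)
  sds <- apply(rm, 2L, stats::sd)
  centred <- sweep(rm, 2L, colMeans(rm))
  out <- as.vector(crossprod(rx, centred)) / (nrow(m) - 1) / sds
  out[sds == 0] <- NA_real_
  unname(out)
}

# shared input checks ---------------------------------------------------

assert_expression <- function(expr) {
  need <- c("gene_id", "sample_id", "tpm_circ", "tpm_linear")
  miss <- setdiff(need, names(expr))
  if (length(miss))
    abort(paste0("expression table is missing column(s): ", paste(miss, collapse = ", ")))
  if (any(!is.finite(expr$tpm_circ)) || any(!is.finite(expr$tpm_linear)))
    abort("expression values must be finite")
  if (any(expr$tpm_circ < 0) || any(expr$tpm_linear < 0))
    abort("TPM values must be non-negative")
  invisible(expr)
}

assert_metadata <- function(meta) {
  need <- c("sample_id", "tissue", "age_weeks")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort(paste0("sample metadata is missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id))
    abort("sample_id values in metadata must be unique")
  invisible(meta)
}

# join expression to metadata restricted to one tissue
tissue_slice <- function(expr, meta, tissue) {
  if (!tissue %in% meta$tissue)
    abort(paste0("tissue '", tissue, "' not present in metadata"))
  ids <- meta$sample_id[meta$tissue == tissue]
  dplyr::filter(expr, .data$sample_id %in% ids)
}
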