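# broom-style accessors for the package's result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy circ_tsi_comparison
#' @export
tidy.circ_tsi_comparison <- function(x, ...) x$per_gene

#' @method glance circ_tsi_comparison
#' @export
glance.circ_tsi_comparison <- function(x, ...) {
  dplyr::bind_cols(x$test,
                   tidyr::pivot_wider(x$high_counts, names_from = "layer",
                                      values_from = "n_high",
                                      names_prefix = "n_high_"))
}

#' @method tidy circ_splicing_contrast
#' @export
tidy.circ_splicing_contrast <- function(x, ...) x$per_gene

#' @method glance circ_splicing_contrast
#' @export
glance.circ_splicing_contrast <- function(x, ...) x$test

#' @method tidy circ_age_trend
#' @export
tidy.circ_age_trend <- function(x, ...) x$samples

#' @method glance circ_age_trend
#' @export
glance.circ_age_trend <- function(x, ...)
  tibble(tissue = x$tissue, rho = x$rho, p_value = x$p_value,
         n = x$n, status = x$status)

#' @method tidy circ_resampling_test
#' @export
tidy.circ_resampling_test <- function(x, ...) x$observed

#' @method glance circ_resampling_test
#' @export
glance.circ_resampling_test <- function(x, ...)
  tibble(statistic = x$observed$statistic, p_value = x$observed$p_value,
         n = x$observed$n, pass_fraction = x$pass_fraction,
         n_resamples = x$n_resamples, alternative = x$alternative,
         universe_size = x$universe_size)

#' @method tidy circ_fraction_bins
#' @export
tidy.circ_fraction_bins <- function(x, ...) x$per_gene

#' @method glance circ_fraction_bins
#' @export
glance.circ_fraction_bins <- function(x, ...) x$trend

#' @method tidy circ_conservation
#' @export
tidy.circ_conservation <- function(x, ...) x$per_circ

#' @method glance circ_conservation
#' @export
glance.circ_conservation <- function(x, ...)
  tidyr::pivot_wider(x$tests, names_from = "codon_pos",
                     values_from = c("ks_stat", "p_value", "n"))

#' @method tidy circ_clustering
#' @export
tidy.circ_clustering <- function(x, ...) x$assignments

#' @method glance circ_clustering
#' @export
glance.circ_clustering <- function(x, ...)
  tibble(n_samples = nrow(x$assignments),
         n_clusters = dplyr::n_distinct(x$assignments$cluster),
         purity = x$purity)
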