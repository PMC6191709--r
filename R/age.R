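resolve_stage_window <- function(stage_window, ages) {
  if (is.numeric(stage_window)) {
    if (length(stage_window) != 2L || diff(stage_window) <= 0)
      abort("numeric stage_window must be an increasing pair of ages")
    return(list(label = paste0(stage_window[1], "-", stage_window[2], "wk"),
                lo = stage_window[1], hi = stage_window[2]))
  }
  switch(stage_window,
    "all" = list(label = "all", lo = -Inf, hi = Inf),
    "2-21wk" = list(label = "2-21wk", lo = 2, hi = 21),
    "21-104wk" = list(label = "21-104wk", lo = 21, hi = 104),
    abort("stage_window must be 'all', '2-21wk', '21-104wk' or a numeric pair"))
}

#' Overall circular-fraction trend with age in one tissue
#'
#' Per sample, the overall circular fraction
#' `sum(TPM_circ) / sum(TPM_circ + TPM_linear)` over all genes; Spearman's
#' rank correlation (midranks over the tied ages) of that value against age
#' across the tissue's samples.
#'
#' @param expression Paired-expression tibble.
#' @param metadata Sample metadata tibble.
#' @param tissue Tissue label.
#' @return A list of class `circ_age_trend`: `samples` (sample_id,
#'   age_weeks, overall_fraction), `rho`, `p_value`, `n`, `status`
#'   (`"ok"` or `"insufficient: fewer than 3 samples"`), `tissue`.
#' @export
overall_fraction_trend <- function(expression, metadata, tissue) {
  assert_expression(expression); assert_metadata(metadata)
  samples <- tissue_slice(expression, metadata, tissue) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(overall_fraction = sum(.data$tpm_circ) /
                       sum(.data$tpm_circ + .data$tpm_linear),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "age_weeks"),
                     by = "sample_id") |>
    dplyr::relocate("age_weeks", .after = "sample_id")
  if (nrow(samples) < 3L) {
    out <- list(samples = samples, rho = NA_real_, p_value = NA_real_,
                n = nrow(samples), status = "insufficient: fewer than 3 samples",
                tissue = tissue)
  } else if (diff(range(samples$overall_fraction)) <= 1e-12) {
    # an (up to rounding) constant fraction carries no trend: rho 0 by
    # convention
    out <- list(samples = samples, rho = 0, p_value = 1,
                n = nrow(samples), status = "ok", tissue = tissue)
  } else {
    st <- spearman_test(samples$age_weeks, samples$overall_fraction)
    out <- list(samples = samples, rho = st$rho, p_value = st$p_value,
                n = st$n, status = "ok", tissue = tissue)
  }
  structure(out, class = "circ_age_trend")
}

#' @export
print.circ_age_trend <- function(x, ...) {
  cat(sprintf("<circ_age_trend> %s: rho = %s, P = %s (n = %d, %s)\n",
              x$tissue, format(x$rho, digits = 3),
              format(x$p_value, digits = 3), x$n, x$status))
  invisible(x)
}

#' Per-gene Spearman correlation between expression and age
#'
#' For every host gene, Spearman's rho of `TPM` against age over the
#' samples of one tissue and stage window, computed for the circular and
#' linear layers. Genes whose expression is all zero (or constant) within
#' the window get `NA` for that layer.
#'
#' @inheritParams overall_fraction_trend
#' @param stage_window `"all"` (default), `"2-21wk"`, `"21-104wk"`, or a
#'   numeric `(lo, hi)` age range in weeks (inclusive).
#' @return Tibble `gene_id`, `rho_circ`, `rho_linear`, `n_samples`,
#'   `stage_window`, `tissue`.
#' @export
per_gene_age_correlation <- function(expression, metadata, tissue,
                                     stage_window = "all") {
  assert_expression(expression); assert_metadata(metadata)
  win <- resolve_stage_window(stage_window, unique(metadata$age_weeks))
  meta_w <- dplyr::filter(metadata, .data$tissue == !!tissue,
                          .data$age_weeks >= win$lo, .data$age_weeks <= win$hi)
  if (nrow(meta_w) < 3L) abort("fewer than 3 samples in the stage window")
  ex <- dplyr::filter(expression, .data$sample_id %in% meta_w$sample_id)
  wide <- function(col) {
    m <- ex |>
      dplyr::select("gene_id", "sample_id", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "sample_id",
                         values_from = dplyr::all_of(col))
    mat <- t(as.matrix(m[, -1, drop = FALSE]))
    colnames(mat) <- m$gene_id
    mat[meta_w$sample_id, , drop = FALSE]
  }
  mc <- wide("tpm_circ"); ml <- wide("tpm_linear")
  tibble(
    gene_id = colnames(mc),
    rho_circ = spearman_rho_cols(meta_w$age_weeks, mc),
    rho_linear = spearman_rho_cols(meta_w$age_weeks, ml),
    n_samples = nrow(meta_w),
    stage_window = win$label,
    tissue = tissue
  )
}

#' Select age-sensitive circRNAs by a correlation threshold
#'
#' Thresholds the circular-layer rho with a strict inequality, e.g.
#' `"rho>0.7"` keeps genes with `rho_circ` strictly above 0.7 and
#' `"rho<-0.6"` those strictly below -0.6.
#'
#' @param results Tibble from [per_gene_age_correlation()].
#' @param rule A string `"rho>x"` or `"rho<x"`.
#' @return The selected rows of `results` (genes with `NA` rho are never
#'   selected), with the rule recorded in `attr(, "rule")`.
#' @export
select_age_sensitive <- function(results, rule = "rho>0.7") {
  m <- regmatches(rule, regexec("^rho([<>])(-?[0-9.]+)$", rule))[[1]]
  if (length(m) != 3L) abort("rule must look like 'rho>0.7' or 'rho<-0.6'")
  thr <- as.numeric(m[3])
  keep <- if (m[2] == ">") results$rho_circ > thr else results$rho_circ < thr
  out <- results[!is.na(keep) & keep, , drop = FALSE]
  attr(out, "rule") <- rule
  out
}

#' Resampling test of circular/linear independence for a selected gene set
#'
#' (a) A one-tailed paired t-test of `rho_circ` versus `rho_linear` over
#' the selected genes; (b) the same test on `n_resamples` uniformly drawn
#' same-size gene sets (without replacement within a set) from the
#' analysed universe -- all genes with defined rho in both layers. The pass
#' fraction is the share of resampled sets significant at `alpha`. A large
#' pass fraction says the circular layer's age correlation exceeds the
#' linear layer's across the repertoire, not just in the selected set.
#'
#' @param results Tibble from [per_gene_age_correlation()] (the universe).
#' @param selected Selected subset from [select_age_sensitive()].
#' @param n_resamples Number of random sets (>= 1; default 1000).
#' @param alternative `"greater"` (circ rho exceeds linear; up-regulated
#'   sets) or `"less"` (down-regulated sets).
#' @param alpha Per-resample significance level (default 0.05).
#' @param seed Optional integer seed governing the whole resampling run.
#' @return A list of class `circ_resampling_test`: `observed` (one-row
#'   tibble: statistic, p_value, mean_difference, n), `pass_fraction`,
#'   `n_resamples`, `alternative`, `universe_size`.
#' @export
resampling_independence_test <- function(results, selected, n_resamples = 1000,
                                         alternative = c("greater", "less"),
                                         alpha = 0.05, seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_resamples < 1L) abort("n_resamples must be >= 1")
  universe <- dplyr::filter(results, !is.na(.data$rho_circ),
                            !is.na(.data$rho_linear))
  if (dplyr::n_distinct(selected$gene_id) > nrow(universe))
    abort("selected set is larger than the analysed universe")
  sel <- dplyr::semi_join(universe, selected, by = "gene_id")
  if (nrow(sel) == 0L) abort("selected set is empty (after requiring defined rho)")
  if (nrow(sel) > nrow(universe))
    abort("selected set is larger than the analysed universe")
  one_test <- function(rc, rl) {
    d <- rc - rl
    if (stats::sd(d) == 0)  # identical layers: no evidence either way
      return(c(statistic = 0, p_value = 1, mean_difference = mean(d)))
    tt <- t.test(rc, rl, paired = TRUE, alternative = alternative)
    c(statistic = unname(tt$statistic), p_value = tt$p.value,
      mean_difference = unname(tt$estimate))
  }
  obs <- one_test(sel$rho_circ, sel$rho_linear)
  run <- function() {
    p <- numeric(n_resamples)
    for (i in seq_len(n_resamples)) {
      idx <- sample.int(nrow(universe), nrow(sel))
      p[i] <- one_test(universe$rho_circ[idx], universe$rho_linear[idx])[["p_value"]]
    }
    p
  }
  p_res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(
    observed = tibble(statistic = obs[["statistic"]], p_value = obs[["p_value"]],
                      mean_difference = obs[["mean_difference"]], n = nrow(sel)),
    pass_fraction = mean(p_res < alpha),
    n_resamples = as.integer(n_resamples),
    alternative = alternative,
    universe_size = nrow(universe)),
    class = "circ_resampling_test")
}

#' @export
print.circ_resampling_test <- function(x, ...) {
  cat(sprintf(
    "<circ_resampling_test> observed t = %.3f (P = %.3g, n = %d, %s)\n",
    x$observed$statistic, x$observed$p_value, x$observed$n, x$alternative))
  cat(sprintf("  pass fraction: %.3f over %d resamples (universe %d genes)\n",
              x$pass_fraction, x$n_resamples, x$universe_size))
  invisible(x)
}
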