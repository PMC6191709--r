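#' Rank-weighted single-sample gene-set score (FAIME-style)
#'
#' Genes are ranked by descending expression (midranks for ties) and each
#' gene weighted `w = exp(-rank / N)` with `N` the universe size; the score
#' is the mean weight over the set minus the mean weight over its
#' complement. Positive scores mean the set's genes concentrate at high
#' expression. Depending only on ranks, the score is invariant under any
#' strictly monotone transform of the expression values, and is exactly 0
#' when all genes are tied.
#'
#' @param expr_sample Tibble with `gene_id` and one expression column
#'   (default `tpm_circ`) for a single sample; the genes present define
#'   the universe.
#' @param gene_set Character vector of gene ids; its intersection with the
#'   universe must be non-empty and proper.
#' @param expr_col Name of the expression column.
#' @return A single numeric score.
#' @examples
#' s <- tibble::tibble(gene_id = letters[1:6], tpm_circ = c(9, 8, 7, 1, 2, 3))
#' faime_score(s, c("a", "b"))  # positive: set at the top of the ranking
#' @export
faime_score <- function(expr_sample, gene_set, expr_col = "tpm_circ") {
  if (!all(c("gene_id", expr_col) %in% names(expr_sample)))
    abort(paste0("expr_sample needs gene_id and ", expr_col, " columns"))
  values <- expr_sample[[expr_col]]
  universe <- expr_sample$gene_id
  in_set <- universe %in% gene_set
  if (!any(in_set)) abort("gene set is empty after intersecting the universe")
  if (all(in_set)) abort("gene-set complement is empty within the universe")
  r <- rank(-values)  # descending, midranks for ties
  w <- exp(-r / length(universe))
  mean(w[in_set]) - mean(w[!in_set])
}

#' Gene-set score matrix across samples
#'
#' Applies [faime_score()] to every sample and gene set.
#'
#' @param expression Paired-expression tibble.
#' @param gene_sets Named list of gene-id vectors.
#' @param expr_col Expression layer to rank (default `tpm_circ`).
#' @return Tibble `set_name`, `sample_id`, `score` (NA for degenerate
#'   sets, with a warning).
#' @export
faime_scores <- function(expression, gene_sets, expr_col = "tpm_circ") {
  assert_expression(expression)
  by_sample <- split(expression, expression$sample_id)
  purrr::imap(gene_sets, function(set, nm) {
    purrr::imap(by_sample, function(df, sid) {
      sc <- tryCatch(faime_score(df, set, expr_col), error = function(e) NA_real_)
      tibble(set_name = nm, sample_id = sid, score = sc)
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}

#' Trend of pathway scores along an ordinal stage axis
#'
#' Spearman correlation of per-sample pathway scores against an ordered
#' stage (for example spermatogonia = 1, spermatocytes = 2,
#' spermatids = 3), per gene set.
#'
#' @param scores Score tibble from [faime_scores()].
#' @param stages Tibble with `sample_id` and ordinal `stage` (numeric or
#'   ordered factor).
#' @return Tibble `set_name`, `rho`, `p_value`, `n`.
#' @export
pathway_trend <- function(scores, stages) {
  if (!all(c("sample_id", "stage") %in% names(stages)))
    abort("stages needs sample_id and stage columns")
  df <- dplyr::inner_join(scores, stages, by = "sample_id")
  df$stage_num <- if (is.numeric(df$stage)) df$stage else as.numeric(ordered(df$stage))
  df |>
    dplyr::group_by(.data$set_name) |>
    dplyr::group_modify(function(d, key) {
      st <- spearman_test(d$stage_num, d$score)
      tibble(rho = st$rho, p_value = st$p_value, n = st$n)
    }) |>
    dplyr::ungroup()
}

#' Fisher's exact enrichment with a hypergeometric Z-score
#'
#' Tests over-representation of `gene_set` within `hit_set` against
#' `universe` via the 2x2 table (in/out of the hit set by in/out of the
#' gene set), reporting the two-sided Fisher exact P, the conditional
#' odds ratio, and the Z-score `(k - E[K]) / sd(K)` where `K` is
#' hypergeometric with `E[K] = nK/N` and
#' `Var(K) = nK(N-K)(N-n) / (N^2 (N-1))`.
#'
#' @param hit_set Character vector of query genes (must lie in `universe`).
#' @param gene_set Character vector defining the annotation set.
#' @param universe Character vector of background genes.
#' @return One-row tibble: `k`, `n_hits`, `set_size`, `universe_size`,
#'   `expected`, `variance`, `z_score`, `odds_ratio`, `p_value`. With a
#'   degenerate table (set empty or equal to the universe) the variance is
#'   0, `z_score` is `NA` and `p_value` 1.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' fisher_enrichment(u[1:10], u[6:15], u)
#' @export
fisher_enrichment <- function(hit_set, gene_set, universe) {
  universe <- unique(universe)
  hit_set <- unique(hit_set)
  if (!all(hit_set %in% universe))
    abort("hit_set must be a subset of the universe")
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(universe); K <- length(gene_set); n <- length(hit_set)
  k <- length(intersect(hit_set, gene_set))
  expected <- n * K / N
  variance <- if (N > 1) n * K * (N - K) * (N - n) / (N^2 * (N - 1)) else 0
  z <- if (variance > 0) (k - expected) / sqrt(variance) else NA_real_
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2L)
  ft <- fisher.test(tab)
  tibble(k = k, n_hits = n, set_size = K, universe_size = N,
         expected = expected, variance = variance, z_score = z,
         odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Enrichment of a hit set over a gene-set collection
#'
#' Runs [fisher_enrichment()] per set and appends Benjamini-Hochberg
#' q-values over the collection.
#'
#' @param hit_set Character vector of query genes.
#' @param gene_sets Named list of gene-id vectors.
#' @param universe Background gene ids.
#' @return Tibble with one row per set (`set_name` first, then the
#'   [fisher_enrichment()] columns and `q_value`).
#' @export
enrich_gene_sets <- function(hit_set, gene_sets, universe) {
  out <- purrr::imap(gene_sets, function(set, nm)
    dplyr::mutate(fisher_enrichment(hit_set, set, universe),
                  set_name = nm, .before = 1L)) |>
    dplyr::bind_rows()
  dplyr::mutate(out, q_value = p.adjust(.data$p_value, method = "BH"))
}

#' Top enriched terms
#'
#' Ranks enrichment results by descending Z-score, then ascending P, then
#' set name (the declared tie-break), and returns the top `k`.
#'
#' @param enrichments Tibble from [enrich_gene_sets()].
#' @param k Number of terms to keep; larger than the table returns all.
#' @return The top rows, ranked.
#' @export
top_terms_report <- function(enrichments, k = 5) {
  enrichments |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$z_score, -Inf)),
                   .data$p_value, .data$set_name) |>
    head(k)
}
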