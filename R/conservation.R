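#' Conservation of circRNA versus linear-only coding bases by codon position
#'
#' For each exonic circRNA, walks the CDS of its host gene's longest
#' transcript in coding order (strand-aware, so codon positions 1/2/3 are
#' assigned on the coding strand), attaches per-base conservation scores,
#' and averages them separately over CDS bases inside the circRNA span and
#' over CDS bases exclusive to the linear transcript. The two groups of
#' per-circRNA means are then compared per codon position with a
#' Kolmogorov-Smirnov test.
#'
#' Host genes without an annotated CDS are excluded (with a message); track
#' positions missing from the conservation table are dropped.
#'
#' @param repertoire Classified repertoire ([build_repertoire()]); only
#'   exonic records are used.
#' @param annotation Feature tibble with `CDS` rows.
#' @param track Conservation tibble (`chrom`, `pos` 1-based, `score`).
#' @return A list of class `circ_conservation`: `per_circ` (circ_id,
#'   host_gene, codon_pos, mean_circ, mean_linear, n_circ_bases,
#'   n_linear_bases) and `tests` (codon_pos, ks_stat, p_value, n).
#' @export
codon_position_scores <- function(repertoire, annotation, track) {
  exonic <- dplyr::filter(repertoire, .data$genomic_class == "exonic",
                          !is.na(.data$host_gene))
  if (nrow(exonic) == 0L) abort("no exonic circRNAs to score")
  cds <- dplyr::filter(annotation, .data$feature == "CDS")
  score_key <- paste(track$chrom, track$pos)

  no_cds <- setdiff(unique(exonic$host_gene), unique(cds$gene_id))
  if (length(no_cds))
    inform(paste0(length(no_cds), " host gene(s) without CDS excluded"))

  rows <- vector("list", nrow(exonic))
  for (i in seq_len(nrow(exonic))) {
    g <- exonic$host_gene[i]
    seg <- cds[cds$gene_id == g, , drop = FALSE]
    if (nrow(seg) == 0L) next
    # longest transcript = maximal summed CDS width
    tx_len <- tapply(seg$end - seg$start + 1L, seg$transcript_id, sum)
    seg <- seg[seg$transcript_id == names(which.max(tx_len)), , drop = FALSE]
    minus <- seg$strand[1] == "-"
    seg <- seg[order(seg$start, decreasing = minus), , drop = FALSE]
    pos <- unlist(Map(function(s, e) if (minus) e:s else s:e, seg$start, seg$end),
                  use.names = FALSE)
    codon_pos <- ((seq_along(pos) - 1L) %% 3L) + 1L
    sc <- track$score[match(paste(seg$chrom[1], pos), score_key)]
    keep <- !is.na(sc)
    in_circ <- pos > exonic$start[i] & pos <= exonic$end[i]
    df <- tibble(codon_pos = codon_pos[keep], score = sc[keep],
                 in_circ = in_circ[keep])
    agg <- df |>
      dplyr::group_by(.data$codon_pos) |>
      dplyr::summarise(
        mean_circ = mean(.data$score[.data$in_circ]),
        mean_linear = mean(.data$score[!.data$in_circ]),
        n_circ_bases = sum(.data$in_circ),
        n_linear_bases = sum(!.data$in_circ), .groups = "drop")
    rows[[i]] <- dplyr::mutate(agg, circ_id = exonic$circ_id[i],
                               host_gene = g, .before = 1L)
  }
  per_circ <- dplyr::bind_rows(rows)
  if (nrow(per_circ) == 0L) abort("no host gene had annotated CDS")

  tests <- per_circ |>
    dplyr::group_by(.data$codon_pos) |>
    dplyr::group_modify(function(df, key) {
      a <- df$mean_circ[is.finite(df$mean_circ)]
      b <- df$mean_linear[is.finite(df$mean_linear)]
      if (length(a) < 1L || length(b) < 1L)
        return(tibble(ks_stat = NA_real_, p_value = NA_real_,
                      n = length(a) + length(b)))
      kt <- suppressWarnings(ks.test(a, b))
      tibble(ks_stat = unname(kt$statistic), p_value = kt$p.value,
             n = length(a) + length(b))
    }) |>
    dplyr::ungroup()

  structure(list(per_circ = per_circ, tests = tests),
            class = "circ_conservation")
}

#' @export
print.circ_conservation <- function(x, ...) {
  cat("<circ_conservation> ", dplyr::n_distinct(x$per_circ$circ_id),
      "circRNAs scored\n")
  print(x$tests)
  invisible(x)
}

#' Classify circRNAs into mammalian-common / rodent-specific / rat-specific
#'
#' Host-gene-level orthology: a circRNA is mammalian-common when its host
#' gene has one-to-one human and mouse orthologs that both carry a circRNA
#' in the foreign repertoires; rodent-specific when only the mouse ortholog
#' does; rat-specific otherwise. Exonic circRNAs only.
#'
#' @param repertoire Classified repertoire tibble.
#' @param orthologs List with `human` and `mouse` tibbles (`gene_id`,
#'   `ortholog_id`).
#' @param foreign List with `human` and `mouse` character vectors of
#'   circRNA-bearing ortholog ids.
#' @return Tibble `circ_id`, `host_gene`, `lineage`.
#' @export
classify_lineage <- function(repertoire, orthologs, foreign) {
  exonic <- dplyr::filter(repertoire, .data$genomic_class == "exonic",
                          !is.na(.data$host_gene))
  has_circ <- function(species) {
    tab <- orthologs[[species]]
    orth <- tab$ortholog_id[match(exonic$host_gene, tab$gene_id)]
    !is.na(orth) & orth %in% foreign[[species]]
  }
  hs <- has_circ("human"); mm <- has_circ("mouse")
  tibble(circ_id = exonic$circ_id, host_gene = exonic$host_gene,
         lineage = dplyr::case_when(
           hs & mm ~ "mammalian_common",
           mm ~ "rodent_specific",
           .default = "rat_specific"))
}

#' Compare exon counts between mammalian-common and younger circRNAs
#'
#' Two-sided Wilcoxon rank-sum test of exon counts, mammalian-common versus
#' the union of rodent-specific and rat-specific circRNAs, with per-class
#' medians. With an empty side the test is skipped.
#'
#' @param repertoire Classified repertoire tibble (exonic records used).
#' @param lineage Lineage tibble from [classify_lineage()].
#' @return A one-row tibble: `status`, `statistic`, `p_value`,
#'   `median_common`, `median_younger`, `n_common`, `n_younger`.
#' @export
compare_exon_counts_by_lineage <- function(repertoire, lineage) {
  df <- dplyr::inner_join(
    dplyr::select(repertoire, "circ_id", "n_exons"),
    lineage, by = "circ_id")
  common <- df$n_exons[df$lineage == "mammalian_common"]
  younger <- df$n_exons[df$lineage != "mammalian_common"]
  if (length(common) == 0L || length(younger) == 0L)
    return(tibble(status = "skipped: empty lineage class",
                  statistic = NA_real_, p_value = NA_real_,
                  median_common = median(common), median_younger = median(younger),
                  n_common = length(common), n_younger = length(younger)))
  wt <- suppressWarnings(wilcox.test(common, younger))
  tibble(status = "ok", statistic = unname(wt$statistic), p_value = wt$p.value,
         median_common = median(common), median_younger = median(younger),
         n_common = length(common), n_younger = length(younger))
}
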