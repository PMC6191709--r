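#' Classify back-splice junctions against a gene annotation
#'
#' A junction is *exonic* when both of its boundaries coincide exactly
#' (0 bp tolerance) with annotated exon boundaries of one gene on the
#' matching strand: the junction start must equal an exon start and the
#' junction end an exon end, the back-splice geometry of an acceptor joined
#' to a downstream donor. *Intronic* junctions overlap a gene without
#' matching exon boundaries; junctions overlapping no gene are
#' *intergenic*. When several genes qualify, the exon-boundary match wins,
#' then the gene with the larger overlap (ties broken by gene id). A
#' junction with strand `"."`/`"*"`/`NA` is classified ignoring strand.
#' Junctions on chromosomes absent from the annotation are intergenic, with
#' a warning.
#'
#' @param junctions Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand`.
#' @param annotation Feature tibble (see [simulate_annotation()] or
#'   [read_annotation_gtf()]).
#' @return The input tibble with `genomic_class`, `host_gene`, `n_exons`
#'   and `spliced_length` columns appended. `n_exons`/`spliced_length` are
#'   the count and summed width of the host-gene exons spanned by the
#'   junction (exonic records only, otherwise 0/`NA`).
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 3, seed = 1))
#' jx <- circ_junctions(ann)
#' classify_junctions(jx[, c("chrom", "start", "end", "strand")], ann)
#' @export
classify_junctions <- function(junctions, annotation) {
  if (!all(c("chrom", "start", "end") %in% names(junctions)))
    abort("junctions need chrom, start, end columns")
  if (any(junctions$start < 0) || any(junctions$start >= junctions$end))
    abort("junction coordinates must satisfy 0 <= start < end")
  if (!"strand" %in% names(junctions)) junctions$strand <- "."

  genes <- dplyr::filter(annotation, .data$feature == "gene")
  exons <- dplyr::filter(annotation, .data$feature == "exon")
  genes_by_chrom <- split(genes, genes$chrom)
  exons_by_gene <- split(exons, exons$gene_id)

  missing_chrom <- setdiff(unique(junctions$chrom), names(genes_by_chrom))
  if (length(missing_chrom))
    warn(paste0("chromosome(s) absent from annotation, treated as intergenic: ",
                paste(missing_chrom, collapse = ", ")))

  n <- nrow(junctions)
  genomic_class <- character(n)
  host_gene <- rep(NA_character_, n)
  n_exons <- integer(n)
  spliced_length <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    js <- junctions$start[i]; je <- junctions$end[i]
    jstrand <- junctions$strand[i]
    cand <- genes_by_chrom[[junctions$chrom[i]]]
    if (!is.null(cand)) {
      ov <- pmin(je, cand$end) - pmax(js, cand$start - 1L)
      cand <- cand[ov > 0, , drop = FALSE]
      ov <- ov[ov > 0]
    }
    if (is.null(cand) || nrow(cand) == 0L) {
      genomic_class[i] <- "intergenic"
      next
    }
    strand_ok <- if (jstrand %in% c("+", "-")) cand$strand == jstrand
                 else rep(TRUE, nrow(cand))
    exonic_gene <- NA_character_
    best_ov <- -1L
    for (k in which(strand_ok)) {
      ex <- exons_by_gene[[cand$gene_id[k]]]
      if (any(ex$start - 1L == js) && any(ex$end == je) && ov[k] > best_ov) {
        exonic_gene <- cand$gene_id[k]
        best_ov <- ov[k]
      }
    }
    if (!is.na(exonic_gene)) {
      ex <- exons_by_gene[[exonic_gene]]
      span <- ex[ex$start - 1L >= js & ex$end <= je, , drop = FALSE]
      genomic_class[i] <- "exonic"
      host_gene[i] <- exonic_gene
      n_exons[i] <- nrow(span)
      spliced_length[i] <- sum(span$end - span$start + 1L)
    } else {
      genomic_class[i] <- "intronic"
      host_gene[i] <- cand$gene_id[which.max(ov)]
    }
  }
  dplyr::mutate(as_tibble(junctions), genomic_class = genomic_class,
                host_gene = host_gene, n_exons = n_exons,
                spliced_length = spliced_length)
}

#' Build the circRNA repertoire from per-sample junction counts
#'
#' Applies the replication filter: a junction enters the repertoire iff it
#' has at least one back-splice read in at least two distinct samples of
#' the same tissue type (pooling ages and sexes within a tissue). Retained
#' junctions are classified against the annotation when one is supplied.
#'
#' @param counts Tibble with `circ_id`, `chrom`, `start`, `end`, `strand`,
#'   `sample_id`, `reads`.
#' @param metadata Sample metadata tibble (`sample_id`, `tissue`, ...).
#' @param annotation Optional feature tibble; `NULL` skips classification.
#' @return A tibble of retained circRNA species sorted by
#'   (chrom, start, end): `circ_id`, coordinates, and classification
#'   columns when annotated.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 8, seed = 5))
#' rep <- build_repertoire(sim$junction_counts, sim$metadata, sim$annotation)
#' table(rep$genomic_class)
#' @export
build_repertoire <- function(counts, metadata, annotation = NULL) {
  assert_metadata(metadata)
  if (nrow(counts) == 0L) abort("junction count table is empty")
  unknown <- setdiff(unique(counts$sample_id), metadata$sample_id)
  if (length(unknown))
    abort(paste0("sample(s) in counts missing from metadata: ",
                 paste(unknown, collapse = ", ")))

  # base-R core: this filter sits inside tight simulation loops
  pos <- which(counts$reads >= 1L)
  circ <- counts$circ_id[pos]
  tissue <- metadata$tissue[match(counts$sample_id[pos], metadata$sample_id)]
  ct <- paste(circ, tissue, sep = "\r")
  first <- !duplicated(paste(ct, counts$sample_id[pos], sep = "\r"))
  per_tissue <- table(ct[first])
  kept <- unique(sub("\r.*", "", names(per_tissue)[per_tissue >= 2L]))

  idx <- which(!duplicated(counts$circ_id) & counts$circ_id %in% kept)
  idx <- idx[order(counts$chrom[idx], counts$start[idx], counts$end[idx])]
  out <- as_tibble(counts[idx, c("circ_id", "chrom", "start", "end", "strand")])
  if (!is.null(annotation)) {
    cls <- classify_junctions(
      dplyr::select(out, "chrom", "start", "end", "strand"), annotation)
    out <- dplyr::bind_cols(
      dplyr::select(out, "circ_id"),
      cls)
  }
  out
}

#' Summarise a circRNA repertoire
#'
#' Per-tissue species counts (a species counts in a tissue when it has
#' reads in at least two samples of that tissue), genomic-class fractions,
#' exon-count and spliced-length histograms over exonic species, and a
#' Spearman test of spliced length against exon count.
#'
#' @param repertoire Classified repertoire from [build_repertoire()].
#' @param counts Junction count tibble (as for [build_repertoire()]).
#' @param metadata Sample metadata tibble.
#' @return A list of class `circ_repertoire_summary`: `per_tissue`,
#'   `class_fractions`, `exon_histogram`, `length_histogram`,
#'   `length_exon_trend`.
#' @export
repertoire_summary <- function(repertoire, counts, metadata) {
  assert_metadata(metadata)
  per_tissue <- counts |>
    dplyr::filter(.data$circ_id %in% repertoire$circ_id, .data$reads >= 1L) |>
    dplyr::left_join(dplyr::select(metadata, "sample_id", "tissue"),
                     by = "sample_id") |>
    dplyr::distinct(.data$circ_id, .data$tissue, .data$sample_id) |>
    dplyr::count(.data$circ_id, .data$tissue) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::count(.data$tissue, name = "n_species")

  class_fractions <- repertoire |>
    dplyr::count(.data$genomic_class) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))

  exonic <- dplyr::filter(repertoire, .data$genomic_class == "exonic")
  exon_histogram <- dplyr::count(exonic, .data$n_exons)
  length_histogram <- exonic |>
    dplyr::mutate(length_bin = 200L * (.data$spliced_length %/% 200L)) |>
    dplyr::count(.data$length_bin)

  trend <- if (nrow(exonic) >= 3L)
    spearman_test(exonic$spliced_length, exonic$n_exons)
  else list(rho = NA_real_, p_value = NA_real_, n = nrow(exonic))

  structure(list(per_tissue = per_tissue, class_fractions = class_fractions,
                 exon_histogram = exon_histogram,
                 length_histogram = length_histogram,
                 length_exon_trend = tibble(rho = trend$rho,
                                            p_value = trend$p_value,
                                            n = trend$n)),
            class = "circ_repertoire_summary")
}

#' @export
print.circ_repertoire_summary <- function(x, ...) {
  cat("<circ_repertoire_summary>\n")
  cat(" species per tissue:\n")
  print(x$per_tissue, n = Inf)
  cat(" class fractions:\n")
  print(x$class_fractions)
  invisible(x)
}
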