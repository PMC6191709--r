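# Standard-format readers/writers. Genomic files go through rtracklayer;
# gene sets through the GMT dialect fgsea reads; tabular data through readr.

#' Write / read a gene annotation as GTF
#'
#' @param annotation Feature tibble (`feature`, `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, `exon_number`).
#' @param path File path.
#' @return `write_annotation_gtf()` returns `path` invisibly;
#'   `read_annotation_gtf()` returns the feature tibble.
#' @export
write_annotation_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$feature,
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    exon_number = annotation$exon_number,
    phase = ifelse(annotation$feature == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  tibble(
    feature = as.character(df$type),
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    chrom = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    exon_number = as.integer(df$exon_number)
  )
}

#' Write / read a per-base conservation track as bedGraph
#'
#' Scores are per-base posterior conservation probabilities in `[0, 1]`
#' (phastCons-like). On disk the track is bedGraph (0-based half-open);
#' in memory it is a tibble of 1-based single positions.
#'
#' @param track Tibble with `chrom`, `pos` (1-based), `score`.
#' @param path File path.
#' @return `write_bedgraph_track()` returns `path` invisibly;
#'   `read_bedgraph_track()` returns the track tibble.
#' @export
write_bedgraph_track <- function(track, path) {
  if (any(track$score < 0 | track$score > 1))
    abort("conservation scores must lie in [0, 1]")
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$pos, width = 1L),
                               score = track$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph_track
#' @export
read_bedgraph_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  tibble(chrom = rep(as.character(df$seqnames), df$width),
         pos = unlist(Map(seq.int, df$start, df$end), use.names = FALSE),
         score = rep(df$score, df$width))
}

#' Write / read gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param path File path.
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` returns the
#'   named list.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read paired circular and linear TPM matrices
#'
#' On disk: two genes-by-samples TSV matrices (first column `gene_id`), one
#' per layer. In memory: one long tibble with `gene_id`, `sample_id`,
#' `tpm_circ`, `tpm_linear`.
#'
#' @param expression Long paired-expression tibble.
#' @param circ_path,linear_path Paths of the two matrices.
#' @return `write_paired_expression()` returns the paths invisibly;
#'   `read_paired_expression()` returns the long tibble.
#' @export
write_paired_expression <- function(expression, circ_path, linear_path) {
  assert_expression(expression)
  wide <- function(col) {
    expression |>
      dplyr::select("gene_id", "sample_id", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(col))
  }
  readr::write_tsv(wide("tpm_circ"), circ_path)
  readr::write_tsv(wide("tpm_linear"), linear_path)
  invisible(c(circ_path, linear_path))
}

#' @rdname write_paired_expression
#' @export
read_paired_expression <- function(circ_path, linear_path) {
  long <- function(path, col) {
    readr::read_tsv(path, show_col_types = FALSE) |>
      tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = col)
  }
  dplyr::inner_join(long(circ_path, "tpm_circ"), long(linear_path, "tpm_linear"),
                    by = c("gene_id", "sample_id"))
}

#' Write a circRNA repertoire as BED6+
#'
#' BED6 columns (chrom, start, end, name, score, strand) followed by
#' `genomic_class`, `host_gene`, `n_exons`, `spliced_length`.
#'
#' @param repertoire Repertoire tibble from [build_repertoire()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_repertoire_bed <- function(repertoire, path) {
  bed <- tibble(
    chrom = repertoire$chrom, start = repertoire$start, end = repertoire$end,
    name = repertoire$circ_id, score = 0L,
    strand = ifelse(repertoire$strand %in% c("+", "-"), repertoire$strand, "."),
    genomic_class = repertoire$genomic_class,
    host_gene = repertoire$host_gene %||% NA_character_,
    n_exons = repertoire$n_exons, spliced_length = repertoire$spliced_length
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
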