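# Shared fixtures, built in code.

# A small simulation config; override any field.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 30, tissues = c("brain", "liver", "testes", "kidney"),
                  seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Hand-built two-gene annotation on chr1 used by the classification tests:
#   gA (+): exons 101-200, 301-400, 501-600, 701-800
#   gB (-): exons 2001-2100, 2301-2400
toy_annotation <- function() {
  tibble::tibble(
    feature = c("gene", rep("exon", 4), rep("CDS", 4),
                "gene", rep("exon", 2), rep("CDS", 2)),
    gene_id = c(rep("gA", 9), rep("gB", 5)),
    transcript_id = c(rep("gA.t1", 9), rep("gB.t1", 5)),
    chrom = "chr1",
    start = c(101, 101, 301, 501, 701, 101, 301, 501, 701,
              2001, 2001, 2301, 2001, 2301),
    end = c(800, 200, 400, 600, 800, 200, 400, 600, 800,
            2400, 2100, 2400, 2100, 2400),
    strand = c(rep("+", 9), rep("-", 5)),
    exon_number = c(NA, 1:4, 1:4, NA, 1:2, 1:2)
  )
}

# junction-count rows: one row per (circ, sample) with reads
toy_counts <- function(circ_samples) {
  purrr::imap(circ_samples, function(samples, cid)
    tibble::tibble(circ_id = cid, chrom = "chr1",
                   start = 100 + 10 * match(cid, names(circ_samples)),
                   end = 1000 + 10 * match(cid, names(circ_samples)),
                   strand = "+", sample_id = samples, reads = 1L)) |>
    dplyr::bind_rows()
}

toy_metadata <- function(tissues = c("brain", "liver"), n_per_tissue = 3) {
  tibble::tibble(
    sample_id = paste0(rep(tissues, each = n_per_tissue), "_s",
                       rep(seq_len(n_per_tissue), length(tissues))),
    tissue = rep(tissues, each = n_per_tissue),
    age_weeks = 2, sex = "M",
    replicate = rep(seq_len(n_per_tissue), length(tissues))
  )
}

# Random junction-count table over a random design, for filter-oracle tests.
random_count_table <- function(n_junctions = 5, n_tissues = 3, n_samples = 6,
                               lambda = 0.7) {
  meta <- tibble::tibble(
    sample_id = paste0("s", seq_len(n_samples)),
    tissue = sample(paste0("t", seq_len(n_tissues)), n_samples, replace = TRUE),
    age_weeks = 2, sex = "M", replicate = seq_len(n_samples))
  counts <- tidyr::expand_grid(circ_id = paste0("c", seq_len(n_junctions)),
                               sample_id = meta$sample_id) |>
    dplyr::mutate(chrom = "chr1",
                  start = 10L * as.integer(sub("c", "", circ_id)),
                  end = start + 100L,
                  strand = "+",
                  reads = stats::rpois(dplyr::n(), lambda))
  list(counts = counts, meta = meta)
}

# Independent brute-force evaluation of the repertoire filter:
# keep a junction iff some tissue has >= 2 distinct samples with >= 1 read.
brute_force_repertoire <- function(counts, meta) {
  kept <- character()
  for (cid in unique(counts$circ_id)) {
    sub <- counts[counts$circ_id == cid & counts$reads >= 1, ]
    tissues <- meta$tissue[match(sub$sample_id, meta$sample_id)]
    for (t in unique(tissues)) {
      if (length(unique(sub$sample_id[tissues == t])) >= 2) {
        kept <- c(kept, cid)
        break
      }
    }
  }
  sort(kept)
}

# Independent midrank + Pearson oracle for Spearman's rho.
midrank_oracle <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

spearman_oracle <- function(x, y) pearson_oracle(midrank_oracle(x), midrank_oracle(y))

# Paired-expression tibble from circ/linear matrices (genes x samples).
expr_from_matrices <- function(circ, linear) {
  stopifnot(identical(dim(circ), dim(linear)))
  tibble::tibble(
    gene_id = rep(rownames(circ), times = ncol(circ)),
    sample_id = rep(colnames(circ), each = nrow(circ)),
    tpm_circ = as.vector(circ),
    tpm_linear = as.vector(linear)
  )
}
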