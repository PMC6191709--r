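# Seed fan-out: each generator stage draws from config$seed plus a fixed
# offset, so a stage rerun alone reproduces its slice of the dataset.
stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Simulate a gene annotation
#'
#' Generates a toy multi-exon gene annotation: `n_genes` genes laid out
#' without overlap on five chromosomes, both strands, each with 2-25 exons
#' and a single transcript whose exons double as its CDS. One circRNA
#' species per gene is defined as a run of consecutive exons whose outer
#' boundaries form the back-splice junction (see [circ_junctions()]).
#'
#' @param config A [sim_config()] object.
#' @return A tibble of features with columns `feature` (gene/exon/CDS),
#'   `gene_id`, `transcript_id`, `chrom`, `start`, `end` (1-based
#'   inclusive, GTF convention), `strand`, `exon_number`.
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 5))
#' table(ann$feature)
#' @export
simulate_annotation <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(stage_seed(config, 1L), {
    n <- config$n_genes
    chroms <- paste0("chr", 1:5)
    chrom <- chroms[((seq_len(n) - 1L) %% 5L) + 1L]
    strand <- ifelse(seq_len(n) %% 2L == 0L, "-", "+")
    n_exons <- sample(2:25, n, replace = TRUE)
    cursor <- setNames(rep(1000L, 5L), chroms)
    rows <- vector("list", n)
    for (g in seq_len(n)) {
      k <- n_exons[g]
      widths <- sample(60:300, k, replace = TRUE)
      widths <- widths - (widths %% 3L)  # exon widths in full codons
      gaps <- sample(200:1500, k, replace = TRUE)
      start <- cursor[[chrom[g]]]
      ex_start <- start + cumsum(c(0L, widths[-k] + gaps[-k]))
      ex_end <- ex_start + widths - 1L
      cursor[[chrom[g]]] <- max(ex_end) + sample(3000:8000, 1L)
      gid <- sprintf("gene%04d", g)
      rows[[g]] <- tibble(
        feature = c("gene", rep(c("exon", "CDS"), each = k)),
        gene_id = gid,
        transcript_id = paste0(gid, ".t1"),
        chrom = chrom[g],
        start = c(min(ex_start), ex_start, ex_start),
        end = c(max(ex_end), ex_end, ex_end),
        strand = strand[g],
        exon_number = c(NA_integer_, seq_len(k), seq_len(k))
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Back-splice junctions planted in a simulated annotation
#'
#' One circRNA species per gene: a deterministic run of consecutive exons
#' (starting at exon 2 where the gene has more than two exons, spanning up
#' to five exons). The junction joins the first spanned exon's start to the
#' last spanned exon's end, reported in 0-based half-open coordinates.
#'
#' @param annotation A feature tibble from [simulate_annotation()].
#' @return A tibble with `circ_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `n_exons`, `spliced_length`.
#' @export
circ_junctions <- function(annotation) {
  exons <- dplyr::filter(annotation, .data$feature == "exon") |>
    dplyr::arrange(.data$gene_id, .data$start)
  exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      k <- nrow(df)
      g <- as.integer(sub("gene", "", key$gene_id))
      i0 <- if (k > 2L) 2L else 1L
      j0 <- min(k, i0 + (g %% 5L) + 1L)
      span <- df[i0:j0, ]
      tibble(
        chrom = span$chrom[1],
        start = min(span$start) - 1L,  # to 0-based half-open
        end = max(span$end),
        strand = span$strand[1],
        n_exons = nrow(span),
        spliced_length = sum(span$end - span$start + 1L)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(circ_id = paste0(.data$chrom, ":", .data$start, "|", .data$end),
                  .before = 1L)
}

#' Simulate paired circular/linear expression with planted effects
#'
#' Draws per-gene linear abundance from a log-normal, then builds the
#' circular layer through the log-odds of the circular fraction:
#' `log-odds = baseline + tissue boost + age terms + noise`, with
#' `TPM_circ = exp(log-odds) * L_g` and `TPM_linear = L_g * exp(noise)`.
#' Age enters as log(weeks); the monotone profile is a linear slope and the
#' rise-then-fall profile a tent in log-age peaking at the third age. The
#' two measurement-noise draws are independent Gaussians of equal SD, so
#' circular and linear layers are exchangeable when no effect is planted.
#'
#' @param config A [sim_config()] object.
#' @return A list with `expression` (tibble: gene_id, sample_id, tpm_circ,
#'   tpm_linear), `metadata` (tibble: sample_id, tissue, age_weeks, sex,
#'   replicate) and `truth` (tibble: gene_id, class, specific_tissue, and
#'   the per-gene generating parameters `linear_tpm`, `baseline_logit`).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 10, seed = 3))
#' head(sim$truth)
#' @export
simulate_expression <- function(config) {
  config <- validate_sim_config(config)
  meta <- sim_metadata(config)
  withr::with_seed(stage_seed(config, 2L), {
    n <- config$n_genes
    n_s <- nrow(meta)
    gene_id <- sprintf("gene%04d", seq_len(n))

    n_ts <- round(config$frac_tissue_specific * n)
    n_up <- round(config$frac_age_up * n)
    n_ud <- round(config$frac_age_updown * n)
    class <- rep("null", n)
    planted <- sample(n, n_ts + n_up + n_ud)
    class[planted[seq_len(n_ts)]] <- "tissue_specific"
    class[planted[n_ts + seq_len(n_up)]] <- "age_up"
    class[planted[n_ts + n_up + seq_len(n_ud)]] <- "age_up_down"
    specific_tissue <- rep(NA_character_, n)
    specific_tissue[class == "tissue_specific"] <-
      sample(config$tissues, n_ts, replace = TRUE)

    L <- rlnorm(n, config$linear_logmean_sd[1], config$linear_logmean_sd[2])

    la <- log(meta$age_weeks)
    ages <- config$ages_weeks
    peak <- ages[min(3L, length(ages))]
    tent <- tent01(la, log(min(ages)), log(peak), log(max(ages)))
    amp <- config$age_slope_logit * (log(peak) - log(min(ages)))

    logodds <- matrix(config$baseline_logit_fraction, n, n_s)
    up_t <- meta$tissue == config$age_up_tissue
    ud_t <- meta$tissue == config$age_updown_tissue
    for (g in which(class == "tissue_specific")) {
      sel <- meta$tissue == specific_tissue[g]
      logodds[g, sel] <- logodds[g, sel] + config$tissue_effect_logit
    }
    for (g in which(class == "age_up"))
      logodds[g, up_t] <- logodds[g, up_t] + config$age_slope_logit * la[up_t]
    for (g in which(class == "age_up_down"))
      logodds[g, ud_t] <- logodds[g, ud_t] + amp * tent[ud_t]
    # tissue-wide drift shared by all genes
    if (config$age_slope_global_logit > 0) {
      gamp <- config$age_slope_global_logit * (log(peak) - log(min(ages)))
      logodds[, up_t] <- logodds[, up_t] +
        rep(config$age_slope_global_logit * la[up_t], each = n)
      logodds[, ud_t] <- logodds[, ud_t] + rep(gamp * tent[ud_t], each = n)
    }

    eta <- matrix(rnorm(n * n_s, 0, config$noise_sd_logit), n, n_s)
    eps <- matrix(rnorm(n * n_s, 0, config$noise_sd_logit), n, n_s)
    tpm_linear <- L * exp(eps)
    tpm_circ <- exp(logodds + eta) * L

    expression <- tibble(
      gene_id = rep(gene_id, times = n_s),
      sample_id = rep(meta$sample_id, each = n),
      tpm_circ = as.vector(tpm_circ),
      tpm_linear = as.vector(tpm_linear)
    )
    truth <- tibble(
      gene_id = gene_id, class = class, specific_tissue = specific_tissue,
      linear_tpm = L, baseline_logit = config$baseline_logit_fraction
    )
    list(expression = expression, metadata = meta, truth = truth)
  })
}

# tent in x rising 0 -> 1 on [lo, mid], falling back to 0 at hi
tent01 <- function(x, lo, mid, hi) {
  up <- (x - lo) / (mid - lo)
  down <- if (hi > mid) (hi - x) / (hi - mid) else rep(1, length(x))
  pmin(pmax(pmin(up, down), 0), 1)
}

sim_metadata <- function(config) {
  grid <- tidyr::expand_grid(
    tissue = config$tissues,
    age_weeks = config$ages_weeks,
    replicate = seq_len(config$replicates_per_cell)
  )
  # sex alternates within a cell; single-sex reproductive tissues
  sex <- ifelse(grid$replicate %% 2L == 1L, "M", "F")
  sex[grid$tissue == "testes"] <- "M"
  sex[grid$tissue == "uterus"] <- "F"
  tibble(
    sample_id = sprintf("%s_%gwk_r%d", grid$tissue, grid$age_weeks, grid$replicate),
    tissue = grid$tissue, age_weeks = grid$age_weeks,
    sex = sex, replicate = grid$replicate
  )
}

#' Simulate back-splice junction read counts
#'
#' Per sample and circRNA species, the junction read count is Poisson with
#' mean `mean_junction_depth * TPM_circ`; with depth 0 every count is 0.
#'
#' @param config A [sim_config()] object.
#' @param expression Expression tibble from [simulate_expression()].
#' @param annotation Feature tibble from [simulate_annotation()] (supplies
#'   the junction coordinates via [circ_junctions()]).
#' @return A tibble with `circ_id`, `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `sample_id`, `reads` (0-based half-open coordinates).
#' @export
simulate_junction_counts <- function(config, expression, annotation) {
  config <- validate_sim_config(config)
  assert_expression(expression)
  jx <- circ_junctions(annotation)
  withr::with_seed(stage_seed(config, 3L), {
    out <- dplyr::left_join(expression, jx, by = "gene_id")
    if (any(is.na(out$circ_id)))
      abort("annotation does not cover every gene in the expression table")
    out$reads <- rpois(nrow(out), config$mean_junction_depth * out$tpm_circ)
    dplyr::select(out, "circ_id", "chrom", "start", "end", "strand",
                  "gene_id", "sample_id", "reads")
  })
}

#' Simulate auxiliary evolutionary and pathway inputs
#'
#' Generates (i) a per-base conservation track over all exon bases, scores
#' in `[0, 1]` with a +0.2 uplift for bases inside the planted circRNA
#' spans (so circular exons are detectably more conserved); (ii) one-to-one
#' human and mouse ortholog tables covering `ortholog_coverage` of genes;
#' (iii) foreign circRNA repertoires listing which ortholog genes carry a
#' circRNA (90% of orthologs); (iv) a gene-set collection whose sets
#' include the planted age-sensitive modules plus random decoys.
#'
#' @param config A [sim_config()] object.
#' @param annotation Feature tibble from [simulate_annotation()].
#' @param truth Truth tibble from [simulate_expression()].
#' @return A list with `conservation` (tibble chrom/pos/score, 1-based),
#'   `orthologs` (list of human/mouse tibbles gene_id/ortholog_id),
#'   `foreign` (list of human/mouse character vectors of circRNA-bearing
#'   ortholog ids) and `gene_sets` (named list of gene-id vectors).
#' @export
simulate_aux_inputs <- function(config, annotation, truth) {
  config <- validate_sim_config(config)
  jx <- circ_junctions(annotation)
  withr::with_seed(stage_seed(config, 4L), {
    exons <- dplyr::filter(annotation, .data$feature == "exon")
    pos <- tibble(
      chrom = rep(exons$chrom, exons$end - exons$start + 1L),
      gene_id = rep(exons$gene_id, exons$end - exons$start + 1L),
      pos = unlist(Map(seq.int, exons$start, exons$end), use.names = FALSE)
    )
    jx_by_gene <- jx[match(pos$gene_id, jx$gene_id), ]
    in_circ <- pos$pos > jx_by_gene$start & pos$pos <= jx_by_gene$end
    score <- 0.8 * rbeta(nrow(pos), 2, 2) + 0.2 * in_circ
    conservation <- tibble(chrom = pos$chrom, pos = pos$pos,
                           score = pmin(pmax(score, 0), 1))

    genes <- truth$gene_id
    orth <- function(prefix) {
      keep <- runif(length(genes)) < config$ortholog_coverage
      tibble(gene_id = genes[keep],
             ortholog_id = paste0(prefix, "_", genes[keep]))
    }
    orthologs <- list(human = orth("hs"), mouse = orth("mm"))
    foreign <- lapply(orthologs, function(tab)
      tab$ortholog_id[runif(nrow(tab)) < 0.9])

    gene_sets <- list(
      age_up_module = truth$gene_id[truth$class == "age_up"],
      age_updown_module = truth$gene_id[truth$class == "age_up_down"],
      tissue_specific_module = truth$gene_id[truth$class == "tissue_specific"]
    )
    gene_sets <- gene_sets[lengths(gene_sets) > 0]
    for (i in 1:5)
      gene_sets[[paste0("random_module_", i)]] <-
        sample(genes, min(20L, length(genes)))
    list(conservation = conservation, orthologs = orthologs,
         foreign = foreign, gene_sets = gene_sets)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running every generator stage from one config.
#'
#' @param config A [sim_config()] object.
#' @return A list: `config`, `annotation`, `junctions`, `expression`,
#'   `metadata`, `truth`, `junction_counts`, `conservation`, `orthologs`,
#'   `foreign`, `gene_sets`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 12, seed = 2))
#' names(sim)
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  annotation <- simulate_annotation(config)
  ex <- simulate_expression(config)
  counts <- simulate_junction_counts(config, ex$expression, annotation)
  aux <- simulate_aux_inputs(config, annotation, ex$truth)
  c(list(config = config, annotation = annotation,
         junctions = circ_junctions(annotation)),
    ex, list(junction_counts = counts), aux)
}
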