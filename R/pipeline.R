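#' Run the full circRNA analysis pipeline
#'
#' Orchestrates the stages `simulate`, `repertoire`, `evolution`,
#' `expression`, `specificity`, `age` and `pathway` in dependency order on
#' a synthetic dataset, writing each stage's tables under `outdir` plus a
#' JSON manifest (seed, parameters, per-file MD5 checksums, stage status).
#' All randomness descends from `config$seed` through fixed per-stage
#' offsets, so a rerun with the same config and seed reproduces every
#' output byte for byte. A failing stage stops the run with an error after
#' writing the manifest of the stages completed so far.
#'
#' @param config A [sim_config()] object, or a path to a YAML file whose
#'   top-level keys are `sim_config()` arguments plus optionally any of
#'   the threshold arguments below and `stages`.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run (subset of the seven
#'   above); disabling all stages succeeds with an empty manifest body.
#' @param tsi_threshold,min_peak_tpm Tissue-specific calling rule.
#' @param age_rule Selection rule for age-sensitive circRNAs.
#' @param n_resamples Resampling-test size.
#' @param top_k Number of enriched terms reported.
#' @return The manifest, invisibly.
#' @examples
#' \donttest{
#' m <- run_pipeline(sim_config(n_genes = 30, seed = 1), tempfile("run"))
#' names(m$stages)
#' }
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "repertoire", "evolution",
                                    "expression", "specificity", "age",
                                    "pathway"),
                         tsi_threshold = 0.8, min_peak_tpm = 1.0,
                         age_rule = "rho>0.7", n_resamples = 200,
                         top_k = 5) {
  if (is.character(config) && length(config) == 1L)
    config <- sim_config_from_yaml(config)
  config <- validate_sim_config(config)
  order <- c("simulate", "repertoire", "evolution", "expression",
             "specificity", "age", "pathway")
  bad <- setdiff(stages, order)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- order[order %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    seed = config$seed,
    parameters = c(unclass(config),
                   list(tsi_threshold = tsi_threshold,
                        min_peak_tpm = min_peak_tpm, age_rule = age_rule,
                        n_resamples = n_resamples)),
    stages = list(), files = list())
  state <- new.env(parent = emptyenv())

  out <- function(name) file.path(outdir, name)
  register <- function(paths) {
    for (p in paths)
      manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  runners <- list(
    simulate = function() {
      sim <- simulate_dataset(config)
      state$sim <- sim
      write_annotation_gtf(sim$annotation, out("annotation.gtf"))
      readr::write_tsv(sim$junction_counts, out("junction_counts.tsv"))
      write_paired_expression(sim$expression, out("tpm_circ.tsv"),
                              out("tpm_linear.tsv"))
      readr::write_tsv(sim$metadata, out("metadata.tsv"))
      readr::write_tsv(sim$truth, out("simulation_truth.tsv"))
      write_bedgraph_track(sim$conservation, out("conservation.bedGraph"))
      readr::write_tsv(sim$orthologs$human, out("orthologs_human.tsv"))
      readr::write_tsv(sim$orthologs$mouse, out("orthologs_mouse.tsv"))
      writeLines(sim$foreign$human, out("foreign_repertoire_human.txt"))
      writeLines(sim$foreign$mouse, out("foreign_repertoire_mouse.txt"))
      write_gmt(sim$gene_sets, out("gene_sets.gmt"))
      register(out(c("annotation.gtf", "junction_counts.tsv", "tpm_circ.tsv",
                     "tpm_linear.tsv", "metadata.tsv", "simulation_truth.tsv",
                     "conservation.bedGraph", "orthologs_human.tsv",
                     "orthologs_mouse.tsv", "foreign_repertoire_human.txt",
                     "foreign_repertoire_mouse.txt", "gene_sets.gmt")))
      list(n_genes = config$n_genes, n_samples = nrow(sim$metadata))
    },
    repertoire = function() {
      sim <- state$sim
      rep <- build_repertoire(sim$junction_counts, sim$metadata, sim$annotation)
      state$repertoire <- rep
      smry <- repertoire_summary(rep, sim$junction_counts, sim$metadata)
      readr::write_tsv(rep, out("repertoire.tsv"))
      write_repertoire_bed(rep, out("repertoire.bed"))
      readr::write_tsv(smry$per_tissue, out("species_per_tissue.tsv"))
      readr::write_tsv(smry$class_fractions, out("class_fractions.tsv"))
      register(out(c("repertoire.tsv", "repertoire.bed",
                     "species_per_tissue.tsv", "class_fractions.tsv")))
      list(n_species = nrow(rep),
           frac_exonic = mean(rep$genomic_class == "exonic"))
    },
    evolution = function() {
      sim <- state$sim
      cons <- codon_position_scores(state$repertoire, sim$annotation,
                                    sim$conservation)
      lin <- classify_lineage(state$repertoire, sim$orthologs, sim$foreign)
      exn <- compare_exon_counts_by_lineage(state$repertoire, lin)
      readr::write_tsv(cons$per_circ, out("conservation_by_codon_position.tsv"))
      readr::write_tsv(cons$tests, out("conservation_ks_tests.tsv"))
      readr::write_tsv(lin, out("lineage_classes.tsv"))
      readr::write_tsv(exn, out("lineage_exon_test.tsv"))
      register(out(c("conservation_by_codon_position.tsv",
                     "conservation_ks_tests.tsv", "lineage_classes.tsv",
                     "lineage_exon_test.tsv")))
      as.list(table(lin$lineage))
    },
    expression = function() {
      sim <- state$sim
      tissues <- unique(sim$metadata$tissue)
      corr <- purrr::map(tissues, function(t)
        circ_linear_correlation(sim$expression, sim$metadata, t)) |>
        dplyr::bind_rows()
      bins <- fraction_by_expression_bin(
        sim$expression, sim$metadata, config$age_up_tissue,
        n_bins = min(10L, config$n_genes))
      hi <- high_expression_counts(sim$expression, sim$metadata)
      pt <- paired_expression_test(sim$expression)
      readr::write_tsv(corr, out("circ_linear_correlations.tsv"))
      readr::write_tsv(bins$per_bin, out("fraction_by_expression_bin.tsv"))
      readr::write_tsv(hi, out("high_expression_counts.tsv"))
      readr::write_tsv(pt, out("paired_expression_test.tsv"))
      register(out(c("circ_linear_correlations.tsv",
                     "fraction_by_expression_bin.tsv",
                     "high_expression_counts.tsv",
                     "paired_expression_test.tsv")))
      list(median_rho = median(corr$rho, na.rm = TRUE),
           bin_trend_rho = bins$trend$rho)
    },
    specificity = function() {
      sim <- state$sim
      cmp <- paired_tsi_comparison(sim$expression, sim$metadata)
      calls <- call_tissue_specific(sim$expression, sim$metadata,
                                    tsi_threshold, min_peak_tpm)
      state$calls <- calls
      readr::write_tsv(cmp$per_gene, out("tsi_table.tsv"))
      readr::write_tsv(glance(cmp), out("tsi_paired_test.tsv"))
      readr::write_tsv(calls, out("tissue_specific_calls.tsv"))
      ctr <- splicing_ratio_contrast(sim$expression, sim$metadata, calls)
      readr::write_tsv(ctr$per_gene, out("splicing_ratio_contrast.tsv"))
      pca <- pca_samples(sim$expression, sim$metadata)
      readr::write_tsv(as_tibble(pca), out("pca_coordinates.tsv"))
      files <- c("tsi_table.tsv", "tsi_paired_test.tsv",
                 "tissue_specific_calls.tsv", "splicing_ratio_contrast.tsv",
                 "pca_coordinates.tsv")
      if (nrow(calls) >= 2L) {
        clu <- cluster_samples(sim$expression, sim$metadata, calls)
        readr::write_tsv(clu$assignments, out("cluster_assignments.tsv"))
        files <- c(files, "cluster_assignments.tsv")
        purity <- clu$purity
      } else purity <- NA_real_
      register(out(files))
      list(n_called = nrow(calls), clustering_purity = purity)
    },
    age = function() {
      sim <- state$sim
      trends <- purrr::map(unique(sim$metadata$tissue), function(t)
        glance(overall_fraction_trend(sim$expression, sim$metadata, t))) |>
        dplyr::bind_rows()
      rho <- per_gene_age_correlation(sim$expression, sim$metadata,
                                      config$age_up_tissue, "all")
      selected <- select_age_sensitive(rho, age_rule)
      state$age_selected <- selected
      state$age_rho <- rho
      readr::write_tsv(trends, out("overall_fraction_trends.tsv"))
      readr::write_tsv(rho, out("age_correlations.tsv"))
      readr::write_tsv(selected, out("age_sensitive_selected.tsv"))
      files <- c("overall_fraction_trends.tsv", "age_correlations.tsv",
                 "age_sensitive_selected.tsv")
      if (nrow(selected) > 0L) {
        rt <- resampling_independence_test(rho, selected, n_resamples,
                                           "greater",
                                           seed = stage_seed(config, 10L))
        readr::write_tsv(glance(rt), out("age_resampling_test.tsv"))
        files <- c(files, "age_resampling_test.tsv")
        pass <- rt$pass_fraction
      } else pass <- NA_real_
      register(out(files))
      list(n_selected = nrow(selected), resampling_pass_fraction = pass)
    },
    pathway = function() {
      sim <- state$sim
      ud <- sim$metadata[sim$metadata$tissue == config$age_updown_tissue, ]
      scores <- faime_scores(
        dplyr::filter(sim$expression, .data$sample_id %in% ud$sample_id),
        sim$gene_sets)
      stages_tbl <- tibble(sample_id = ud$sample_id,
                           stage = match(ud$age_weeks,
                                         sort(unique(ud$age_weeks))))
      trend <- pathway_trend(scores, stages_tbl)
      selected <- state$age_selected
      universe <- state$age_rho$gene_id[!is.na(state$age_rho$rho_circ)]
      enr <- enrich_gene_sets(intersect(selected$gene_id, universe),
                              sim$gene_sets, universe)
      readr::write_tsv(scores, out("pathway_scores.tsv"))
      readr::write_tsv(trend, out("pathway_trends.tsv"))
      readr::write_tsv(enr, out("pathway_enrichment.tsv"))
      readr::write_tsv(top_terms_report(enr, top_k), out("top_terms.tsv"))
      register(out(c("pathway_scores.tsv", "pathway_trends.tsv",
                     "pathway_enrichment.tsv", "top_terms.tsv")))
      list(n_sets = length(sim$gene_sets),
           top_term = top_terms_report(enr, 1)$set_name)
    }
  )

  needs <- list(repertoire = "simulate", evolution = c("simulate", "repertoire"),
                expression = "simulate", specificity = "simulate",
                age = "simulate", pathway = c("simulate", "age"))
  for (st in stages) {
    miss <- setdiff(needs[[st]] %||% character(), stages)
    if (length(miss))
      abort(paste0("stage '", st, "' needs stage(s): ", paste(miss, collapse = ", ")))
  }

  for (st in stages) {
    res <- tryCatch(runners[[st]](), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- list(status = "failed",
                                    error = conditionMessage(res))
      save_manifest()
      abort(paste0("pipeline stage '", st, "' failed: ",
                   conditionMessage(res)))
    }
    manifest$stages[[st]] <- c(list(status = "ok"), res)
  }
  save_manifest()
  invisible(manifest)
}

#' Read a simulation/pipeline config from YAML
#'
#' Top-level keys matching [sim_config()] arguments are passed through;
#' unknown keys are ignored (the pipeline-level thresholds are read by the
#' command-line wrapper, not here).
#'
#' @param path YAML file path.
#' @return A `circ_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  keep <- intersect(names(y), names(formals(sim_config)))
  do.call(sim_config, y[keep])
}
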