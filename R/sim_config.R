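#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator. The defaults
#' emulate a body-wide rRNA-depleted RNA-seq design: 11 tissues sampled at
#' four ages (2, 6, 21 and 104 weeks) with four replicates per tissue/age
#' cell. Host-gene linear abundance is log-normal; each host gene carries a
#' single circRNA species whose circular fraction lives on the logit scale,
#' where tissue-specific boosts and age slopes are planted.
#'
#' Planted gene classes (in proportions `frac_tissue_specific`,
#' `frac_age_up`, `frac_age_updown`, remainder null):
#' * `tissue_specific`: the circular fraction gains `tissue_effect_logit`
#'   logits in one randomly assigned tissue.
#' * `age_up`: in `age_up_tissue` (brain-like), the log-odds of the circular
#'   fraction grow by `age_slope_logit` per log-week, a monotone
#'   accumulation profile.
#' * `age_up_down`: in `age_updown_tissue` (testes-like), the log-odds
#'   follow a tent in log-age peaking at the third age, i.e. a rise through
#'   sexual maturity followed by a decline in aged animals.
#'
#' `age_slope_global_logit` adds a mild tissue-wide version of the same two
#' profiles (monotone in the brain-like tissue, tent in the testes-like
#' tissue) to every gene, so the whole-tissue circular fraction trends with
#' age the way brain and testes do; set it to 0 for a global null.
#'
#' `noise_sd_logit` is a symmetric per-sample measurement noise: an
#' independent Gaussian of this SD is added to the circular log-odds and to
#' the linear log-abundance. Symmetry makes the two layers exchangeable
#' under the null, so paired circ-versus-linear comparisons are calibrated.
#'
#' @param n_genes Number of host genes (one circRNA species each).
#' @param tissues Character vector of tissue labels (at least 2).
#' @param ages_weeks Increasing ages in weeks (at least 2).
#' @param replicates_per_cell Replicates per tissue/age combination.
#' @param seed Integer RNG seed; fixes every generated byte.
#' @param linear_logmean_sd Length-2 numeric: meanlog and sdlog of the
#'   per-gene log-normal linear TPM.
#' @param baseline_logit_fraction Mean logit of the circular fraction.
#' @param tissue_effect_logit Planted tissue boost, logits (>= 0).
#' @param age_slope_logit Planted per-log-week slope for age-sensitive genes.
#' @param age_slope_global_logit Tissue-wide age drift shared by all genes
#'   in the brain-like/testes-like tissues (>= 0).
#' @param noise_sd_logit Per-sample noise SD applied to both layers (>= 0).
#' @param frac_tissue_specific,frac_age_up,frac_age_updown Proportions of
#'   genes planted in each class; must sum to at most 1.
#' @param mean_junction_depth Scale of back-splice junction coverage: the
#'   Poisson mean of junction reads is `mean_junction_depth * TPM_circ`.
#' @param ortholog_coverage Fraction of host genes given one-to-one human
#'   and mouse orthologs in the auxiliary tables.
#' @param age_up_tissue,age_updown_tissue Tissues carrying the monotone and
#'   tent-shaped age profiles; must be members of `tissues`.
#' @return A validated `circ_sim_config` list.
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 7)
#' cfg$tissues
#' @export
sim_config <- function(n_genes = 200,
                       tissues = c("adrenal", "brain", "heart", "kidney", "liver",
                                   "lung", "muscle", "spleen", "thymus", "testes",
                                   "uterus"),
                       ages_weeks = c(2, 6, 21, 104),
                       replicates_per_cell = 4,
                       seed = 1,
                       linear_logmean_sd = c(2, 1),
                       baseline_logit_fraction = -2,
                       tissue_effect_logit = 3,
                       age_slope_logit = 0.5,
                       age_slope_global_logit = 0.1,
                       noise_sd_logit = 0.3,
                       frac_tissue_specific = 0.15,
                       frac_age_up = 0.15,
                       frac_age_updown = 0.10,
                       mean_junction_depth = 0.5,
                       ortholog_coverage = 0.8,
                       age_up_tissue = NULL,
                       age_updown_tissue = NULL) {
  cfg <- list(
    n_genes = n_genes, tissues = as.character(tissues),
    ages_weeks = as.numeric(ages_weeks),
    replicates_per_cell = as.integer(replicates_per_cell),
    seed = as.integer(seed),
    linear_logmean_sd = as.numeric(linear_logmean_sd),
    baseline_logit_fraction = baseline_logit_fraction,
    tissue_effect_logit = tissue_effect_logit,
    age_slope_logit = age_slope_logit,
    age_slope_global_logit = age_slope_global_logit,
    noise_sd_logit = noise_sd_logit,
    frac_tissue_specific = frac_tissue_specific,
    frac_age_up = frac_age_up,
    frac_age_updown = frac_age_updown,
    mean_junction_depth = mean_junction_depth,
    ortholog_coverage = ortholog_coverage,
    age_up_tissue = age_up_tissue %||%
      (if ("brain" %in% tissues) "brain" else tissues[[1]]),
    age_updown_tissue = age_updown_tissue %||%
      (if ("testes" %in% tissues) "testes" else tissues[[length(tissues)]])
  )
  class(cfg) <- "circ_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid simulation config: ", msg))
  chk(is.numeric(cfg$n_genes) && length(cfg$n_genes) == 1 && cfg$n_genes >= 1 &&
        cfg$n_genes == floor(cfg$n_genes), "n_genes must be a positive integer")
  chk(length(cfg$tissues) >= 2 && !anyDuplicated(cfg$tissues),
      "at least 2 distinct tissues are required")
  chk(length(cfg$ages_weeks) >= 2 && all(cfg$ages_weeks > 0) &&
        !is.unsorted(cfg$ages_weeks, strictly = TRUE),
      "ages_weeks must be >= 2 strictly increasing positive values")
  chk(cfg$replicates_per_cell >= 1, "replicates_per_cell must be positive")
  chk(length(cfg$linear_logmean_sd) == 2 && cfg$linear_logmean_sd[2] >= 0,
      "linear_logmean_sd must be (meanlog, sdlog >= 0)")
  chk(cfg$tissue_effect_logit >= 0, "tissue_effect_logit must be >= 0")
  chk(cfg$age_slope_global_logit >= 0, "age_slope_global_logit must be >= 0")
  chk(cfg$noise_sd_logit >= 0, "noise_sd_logit must be >= 0")
  fr <- c(cfg$frac_tissue_specific, cfg$frac_age_up, cfg$frac_age_updown)
  chk(all(fr >= 0) && all(fr <= 1) && sum(fr) <= 1,
      "planted-class proportions must be in [0,1] and sum to <= 1")
  chk(cfg$mean_junction_depth >= 0, "mean_junction_depth must be >= 0")
  chk(cfg$ortholog_coverage >= 0 && cfg$ortholog_coverage <= 1,
      "ortholog_coverage must be in [0,1]")
  chk(cfg$age_up_tissue %in% cfg$tissues, "age_up_tissue must be one of tissues")
  chk(cfg$age_updown_tissue %in% cfg$tissues,
      "age_updown_tissue must be one of tissues")
  cfg
}

#' @export
print.circ_sim_config <- function(x, ...) {
  cat("<circ_sim_config>\n")
  cat("  genes:", x$n_genes, " tissues:", length(x$tissues),
      " ages:", paste(x$ages_weeks, collapse = "/"),
      " reps:", x$replicates_per_cell, "\n")
  cat("  baseline logit:", x$baseline_logit_fraction,
      " tissue boost:", x$tissue_effect_logit,
      " age slope:", x$age_slope_logit, "\n")
  cat("  planted fractions: ts =", x$frac_tissue_specific,
      ", age_up =", x$frac_age_up, ", age_up_down =", x$frac_age_updown, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
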