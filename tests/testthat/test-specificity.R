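test_that("tau follows its closed form on the canonical examples", {
  expect_equal(tsi(c(10, 0, 0, 0)), 1)
  expect_equal(tsi(c(5, 5, 5)), 0)
  expect_equal(tsi(c(10, 5, 0)), 0.75)
  expect_true(is.na(tsi(c(0, 0, 0))))
  expect_error(tsi(5), "at least 2")
  expect_error(tsi(c(-1, 2)), "non-negative")
})

test_that("tau is bounded, scale-invariant and monotone in the peak", {
  withr::local_seed(11)
  for (i in 1:300) {
    x <- runif(sample(2:12, 1), 0, 100)
    t0 <- tsi(x)
    expect_gte(t0, 0); expect_lte(t0, 1)
    expect_equal(tsi(x * runif(1, 0.01, 100)), t0, tolerance = 1e-12)
    # raising the peak (others fixed) never lowers tau
    x2 <- x
    x2[which.max(x)] <- max(x) * 1.5
    expect_gte(tsi(x2), t0 - 1e-12)
  }
})

test_that("identical layers give all-zero paired differences", {
  sim <- simulate_expression(tiny_config(n_genes = 10))
  expr <- dplyr::mutate(sim$expression, tpm_circ = tpm_linear)
  cmp <- paired_tsi_comparison(expr, sim$metadata)
  expect_match(cmp$test$status, "degenerate")
  expect_equal(cmp$test$statistic, 0)
  expect_equal(cmp$per_gene$tsi_circ, cmp$per_gene$tsi_linear)
})

test_that("planted tissue-specific circ effects raise circular TSI significantly", {
  sim <- simulate_expression(sim_config(n_genes = 100, seed = 12))
  cmp <- paired_tsi_comparison(sim$expression, sim$metadata)
  expect_equal(cmp$test$status, "ok")
  expect_lt(cmp$test$p_value, 1e-6)
  hc <- tidyr::pivot_wider(cmp$high_counts, names_from = layer,
                           values_from = n_high)
  expect_gt(hc$circ, hc$linear)
})

test_that("single-gene input skips the paired test with a status", {
  sim <- simulate_expression(tiny_config(n_genes = 1))
  cmp <- paired_tsi_comparison(sim$expression, sim$metadata)
  expect_match(cmp$test$status, "skipped")
})

test_that("tissue-specific calling applies both the TSI and expression floors", {
  meta <- toy_metadata(tissues = c("t1", "t2", "t3"), n_per_tissue = 2)
  circ <- rbind(
    gA = c(10, 10, 0, 0, 0, 0),    # TSI 1, peak 10 -> called for t1
    gB = c(4, 4, 4, 4, 4, 4),      # TSI 0 -> not called
    gC = c(0.4, 0.4, 0, 0, 0, 0))  # TSI 1 but peak below floor -> not called
  colnames(circ) <- meta$sample_id
  lin <- matrix(5, 3, 6, dimnames = dimnames(circ))
  calls <- call_tissue_specific(expr_from_matrices(circ, lin), meta)
  expect_equal(calls$gene_id, "gA")
  expect_equal(calls$tissue, "t1")
})

test_that("planted tissue-specific genes are recovered with their tissue", {
  cfg <- sim_config(n_genes = 120, seed = 13)
  sim <- simulate_expression(cfg)
  calls <- call_tissue_specific(sim$expression, sim$metadata)
  planted <- dplyr::filter(sim$truth, class == "tissue_specific")
  hit <- dplyr::inner_join(planted, calls, by = "gene_id")
  expect_gte(nrow(hit) / nrow(planted), 0.9)
  expect_true(all(hit$tissue == hit$specific_tissue))
})

test_that("splicing-ratio contrast separates in-tissue from out-tissue fractions", {
  cfg <- tiny_config(n_genes = 40, seed = 14, noise_sd_logit = 0,
                     age_slope_global_logit = 0)
  sim <- simulate_expression(cfg)
  calls <- call_tissue_specific(sim$expression, sim$metadata)
  ctr <- splicing_ratio_contrast(sim$expression, sim$metadata, calls)
  # zero noise: every planted gene has strictly higher in-tissue fraction
  expect_true(all(ctr$per_gene$in_fraction > ctr$per_gene$out_fraction))
  expect_lt(ctr$test$p_value, 0.05)
  # the linear layer shows the opposite pattern
  ctr_lin <- splicing_ratio_contrast(sim$expression, sim$metadata, calls,
                                     layer = "linear")
  expect_true(all(ctr_lin$per_gene$in_fraction < ctr_lin$per_gene$out_fraction))
})

test_that("a constant fraction yields all-zero contrast differences", {
  meta <- toy_metadata(tissues = c("t1", "t2"), n_per_tissue = 2)
  lin <- matrix(rep(c(10, 20, 30, 40), each = 4), 4, byrow = FALSE,
                dimnames = list(paste0("g", 1:4), meta$sample_id))
  expr <- expr_from_matrices(lin, lin)  # fraction 0.5 everywhere
  calls <- tibble::tibble(gene_id = paste0("g", 1:4), tissue = "t1")
  ctr <- splicing_ratio_contrast(expr, meta, calls)
  expect_match(ctr$test$status, "degenerate")
})

test_that("PCA coordinates are stable under duplication and gene order", {
  sim <- simulate_expression(tiny_config(n_genes = 25, seed = 15))
  pca <- pca_samples(sim$expression, sim$metadata)
  # duplicated samples land on identical coordinates
  dup_ids <- sim$metadata$sample_id[1:2]
  expr_dup <- sim$expression |>
    dplyr::filter(sample_id == dup_ids[1]) |>
    dplyr::mutate(sample_id = dup_ids[2]) |>
    dplyr::bind_rows(dplyr::filter(sim$expression, sample_id != dup_ids[2]))
  p2 <- pca_samples(expr_dup, sim$metadata)
  xy <- p2[match(dup_ids, p2$sample_id), c("PC1", "PC2")]
  expect_equal(xy[1, ], xy[2, ], ignore_attr = TRUE)

  # gene order is irrelevant
  shuffled <- sim$expression[sample(nrow(sim$expression)), ]
  p3 <- pca_samples(shuffled, sim$metadata)
  expect_equal(dplyr::arrange(as.data.frame(p3), sample_id)[, c("PC1", "PC2")],
               dplyr::arrange(as.data.frame(pca), sample_id)[, c("PC1", "PC2")],
               tolerance = 1e-8)
})

test_that("well-separated tissue blocks cluster perfectly at zero noise", {
  cfg <- tiny_config(n_genes = 30, seed = 16, noise_sd_logit = 0,
                     age_slope_logit = 0, age_slope_global_logit = 0,
                     frac_age_up = 0, frac_age_updown = 0,
                     frac_tissue_specific = 0.5)
  sim <- simulate_expression(cfg)
  calls <- call_tissue_specific(sim$expression, sim$metadata)
  clu <- cluster_samples(sim$expression, sim$metadata, calls)
  called_tissues <- unique(calls$tissue)
  pure <- clu$assignments |>
    dplyr::filter(tissue %in% called_tissues) |>
    dplyr::group_by(tissue) |>
    dplyr::summarise(one = dplyr::n_distinct(cluster))
  expect_true(all(pure$one == 1))
})
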