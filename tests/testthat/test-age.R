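test_that("spearman_rho equals the midrank Pearson oracle on tied data", {
  withr::local_seed(21)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(c(2, 6, 21, 104), n, replace = TRUE)  # heavy ties
    y <- round(rnorm(n), 1)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("overall fraction trend handles constant, tied and planted cases", {
  meta <- toy_metadata(tissues = "brain", n_per_tissue = 4)
  # constant fraction -> rho 0 by convention, non-significant
  lin <- matrix(5, 4, 4, dimnames = list(paste0("g", 1:4), meta$sample_id))
  res <- overall_fraction_trend(expr_from_matrices(lin, lin), meta, "brain")
  expect_equal(res$rho, 0)
  expect_equal(res$p_value, 1)

  # fewer than 3 samples in the tissue -> flagged
  meta1 <- toy_metadata(tissues = "brain", n_per_tissue = 1)
  res1 <- overall_fraction_trend(
    expr_from_matrices(lin[, 1, drop = FALSE], lin[, 1, drop = FALSE]),
    meta1, "brain")
  expect_match(res1$status, "insufficient")
})

test_that("with tied ages the trend rho equals the midrank maximum, per oracle", {
  # 4 ages x 3 replicates; overall fraction strictly ordered by age,
  # equal within age
  ages <- rep(c(2, 6, 21, 104), each = 3)
  meta <- tibble::tibble(sample_id = paste0("s", 1:12), tissue = "brain",
                         age_weeks = ages, sex = "M", replicate = rep(1:3, 4))
  frac <- rep(c(0.1, 0.2, 0.3, 0.4), each = 3)
  circ <- matrix(rep(frac, each = 2) * 10, 2, byrow = FALSE,
                 dimnames = list(c("g1", "g2"), meta$sample_id))
  lin <- 10 - circ
  res <- overall_fraction_trend(expr_from_matrices(circ, lin), meta, "brain")
  # matching tie structures: the midrank correlation attains exactly 1
  expect_equal(res$rho, spearman_oracle(ages, frac), tolerance = 1e-12)
  expect_equal(res$rho, 1)

  # strictly increasing fraction against tied ages: capped below 1 at the
  # midrank maximum, which the independent oracle pins down
  frac2 <- seq(0.1, 0.4, length.out = 12)
  circ2 <- matrix(rep(frac2, each = 2) * 10, 2, byrow = FALSE,
                  dimnames = dimnames(circ))
  res2 <- overall_fraction_trend(expr_from_matrices(circ2, 10 - circ2),
                                 meta, "brain")
  expect_equal(res2$rho, spearman_oracle(ages, frac2), tolerance = 1e-12)
  expect_lt(res2$rho, 1)
})

test_that("the brain-like tissue shows a positive significant trend at defaults", {
  sim <- simulate_expression(sim_config(n_genes = 100, seed = 22))
  res <- overall_fraction_trend(sim$expression, sim$metadata, "brain")
  expect_gt(res$rho, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("per-gene age correlation is exact for deterministic profiles", {
  ages <- rep(c(2, 6, 21, 104), each = 2)
  meta <- tibble::tibble(sample_id = paste0("s", 1:8), tissue = "brain",
                         age_weeks = ages, sex = "M", replicate = rep(1:2, 4))
  circ <- rbind(g1 = ages, g2 = rev(ages))
  colnames(circ) <- meta$sample_id
  lin <- matrix(rlnorm(16), 2, 8, dimnames = dimnames(circ))
  res <- per_gene_age_correlation(expr_from_matrices(circ, lin), meta, "brain")
  r1 <- res[res$gene_id == "g1", ]
  expect_equal(r1$rho_circ, 1)
  expect_equal(res$rho_circ[res$gene_id == "g2"], -1)
  expect_equal(r1$n_samples, 8L)

  # stage windows restrict to the window's samples
  resw <- per_gene_age_correlation(expr_from_matrices(circ, lin), meta,
                                   "brain", "21-104wk")
  expect_equal(unique(resw$n_samples), 4L)
  expect_equal(unique(resw$stage_window), "21-104wk")
})

test_that("age-independent genes stay near zero correlation", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:16), tissue = "brain",
                         age_weeks = rep(c(2, 6, 21, 104), each = 4),
                         sex = "M", replicate = rep(1:4, 4))
  withr::local_seed(23)
  n <- 400
  circ <- matrix(rlnorm(n * 16), n,
                 dimnames = list(paste0("g", 1:n), meta$sample_id))
  lin <- matrix(rlnorm(n * 16), n, dimnames = dimnames(circ))
  res <- per_gene_age_correlation(expr_from_matrices(circ, lin), meta, "brain")
  expect_lt(abs(mean(res$rho_circ)), 3 / sqrt(n * 15))
  expect_true(all(abs(res$rho_circ) <= 1))
})

test_that("selection by rho rule is strict and direction-aware", {
  res <- tibble::tibble(gene_id = paste0("g", 1:4),
                        rho_circ = c(0.9, 0.71, 0.7, 0.5),
                        rho_linear = 0, n_samples = 16L,
                        stage_window = "all", tissue = "brain")
  sel <- select_age_sensitive(res, "rho>0.7")
  expect_equal(sel$gene_id, c("g1", "g2"))  # 0.7 itself is excluded
  expect_equal(nrow(select_age_sensitive(res, "rho<-0.6")), 0)
  expect_equal(nrow(select_age_sensitive(res[0, ], "rho>0.7")), 0)
  expect_error(select_age_sensitive(res, "rho=0.7"), "rule")
})

test_that("resampling test validates inputs and is deterministic under seed", {
  withr::local_seed(24)
  res <- tibble::tibble(gene_id = paste0("g", 1:50),
                        rho_circ = rnorm(50, 0.2, 0.2),
                        rho_linear = rnorm(50, 0, 0.2),
                        n_samples = 16L, stage_window = "all", tissue = "brain")
  sel <- res[1:10, ]
  expect_error(resampling_independence_test(res[1:5, ], sel), "larger")
  r1 <- resampling_independence_test(res, sel, n_resamples = 1, seed = 9)
  expect_true(r1$pass_fraction %in% c(0, 1))
  r2 <- resampling_independence_test(res, sel, n_resamples = 1, seed = 9)
  expect_identical(r1$pass_fraction, r2$pass_fraction)
})

test_that("identical layers give a zero observed statistic", {
  res <- tibble::tibble(gene_id = paste0("g", 1:30),
                        rho_circ = seq(-0.5, 0.5, length.out = 30),
                        rho_linear = seq(-0.5, 0.5, length.out = 30),
                        n_samples = 16L, stage_window = "all", tissue = "brain")
  rt <- resampling_independence_test(res, res[1:10, ], n_resamples = 5, seed = 1)
  expect_equal(rt$observed$statistic, 0)
  expect_equal(rt$pass_fraction, 0)
})

test_that("symmetric null differences pass at roughly the nominal rate", {
  withr::local_seed(25)
  res <- tibble::tibble(gene_id = paste0("g", 1:200),
                        rho_circ = rnorm(200, 0, 0.25),
                        rho_linear = rnorm(200, 0, 0.25),
                        n_samples = 16L, stage_window = "all", tissue = "brain")
  rt <- resampling_independence_test(res, res[1:30, ], n_resamples = 400,
                                     seed = 2)
  expect_lt(rt$pass_fraction, 0.15)
})

test_that("planted circ-only age effects give sensitivity and a high pass fraction", {
  cfg <- sim_config(n_genes = 200, seed = 26)
  sim <- simulate_expression(cfg)
  res <- per_gene_age_correlation(sim$expression, sim$metadata, "brain")
  sel <- select_age_sensitive(res, "rho>0.7")
  planted <- sim$truth$gene_id[sim$truth$class == "age_up"]
  expect_gte(mean(planted %in% sel$gene_id), 0.8)
  rt <- resampling_independence_test(res, sel, n_resamples = 200,
                                     alternative = "greater", seed = 3)
  expect_gt(rt$pass_fraction, 0.95)
  expect_lt(rt$observed$p_value, 0.05)
})

test_that("rise-then-fall genes split by stage window in the testes-like tissue", {
  cfg <- sim_config(n_genes = 150, seed = 27)
  sim <- simulate_expression(cfg)
  planted <- sim$truth$gene_id[sim$truth$class == "age_up_down"]
  up <- per_gene_age_correlation(sim$expression, sim$metadata, "testes", "2-21wk")
  down <- per_gene_age_correlation(sim$expression, sim$metadata, "testes", "21-104wk")
  sel_up <- select_age_sensitive(up, "rho>0.6")
  sel_down <- select_age_sensitive(down, "rho<-0.6")
  expect_gte(mean(planted %in% sel_up$gene_id), 0.8)
  expect_gte(mean(planted %in% sel_down$gene_id), 0.8)
})
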