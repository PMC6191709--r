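faime_fixture <- function(values, ids = letters[seq_along(values)]) {
  tibble::tibble(gene_id = ids, tpm_circ = values)
}

test_that("uniform expression scores exactly zero and validates degenerate sets", {
  s <- faime_fixture(rep(3, 8))
  expect_equal(faime_score(s, c("a", "b", "c")), 0)
  expect_error(faime_score(s, c("zz")), "empty")
  expect_error(faime_score(s, letters[1:8]), "complement")
})

test_that("the top-k set maximises the score over all size-k subsets", {
  s <- faime_fixture(c(60, 50, 40, 30, 20, 10))
  k <- 2
  target <- faime_score(s, c("a", "b"))
  expect_gt(target, 0)
  # brute force over all C(6,2) subsets
  combos <- utils::combn(s$gene_id, k, simplify = FALSE)
  scores <- vapply(combos, function(set) faime_score(s, set), numeric(1))
  expect_equal(max(scores), target)
  expect_equal(sum(scores >= target), 1L)  # strict ordering: unique maximiser
})

test_that("the score is rank-based: invariant under monotone transforms", {
  withr::local_seed(31)
  v <- rlnorm(20, 1, 1)
  s <- faime_fixture(v, paste0("g", 1:20))
  set <- paste0("g", c(2, 5, 9, 13))
  base <- faime_score(s, set)
  for (f in list(function(x) x^2, log1p, function(x) 5 * x + 2, rank)) {
    expect_equal(faime_score(dplyr::mutate(s, tpm_circ = f(v)), set), base,
                 tolerance = 1e-12)
  }
})

test_that("swapping set and complement negates the score", {
  withr::local_seed(32)
  v <- rnorm(15)
  s <- faime_fixture(v, paste0("g", 1:15))
  set <- paste0("g", 1:6)
  comp <- setdiff(s$gene_id, set)
  expect_equal(faime_score(s, comp), -faime_score(s, set), tolerance = 1e-12)
})

test_that("score matrices cover every sample and flag degenerate sets as NA", {
  sim <- simulate_expression(tiny_config(n_genes = 20, seed = 33))
  sets <- list(good = paste0("gene", sprintf("%04d", 1:5)), bad = "nope")
  sc <- faime_scores(sim$expression, sets)
  expect_equal(nrow(sc), 2 * dplyr::n_distinct(sim$expression$sample_id))
  expect_true(all(is.na(sc$score[sc$set_name == "bad"])))
  expect_true(all(is.finite(sc$score[sc$set_name == "good"])))
})

test_that("pathway trends follow the stage ordering", {
  sc <- tibble::tibble(set_name = "s1", sample_id = paste0("x", 1:6),
                       score = 1:6)
  stages <- tibble::tibble(sample_id = paste0("x", 1:6), stage = rep(1:3, each = 2))
  expect_equal(pathway_trend(sc, stages)$rho, spearman_oracle(rep(1:3, each = 2), 1:6))

  # 3 stages, one sample each: rho enumerates over the 3! orderings
  stages1 <- tibble::tibble(sample_id = paste0("x", 1:3), stage = 1:3)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rhos <- vapply(perms, function(p) {
    sc1 <- tibble::tibble(set_name = "s", sample_id = paste0("x", 1:3), score = p)
    pathway_trend(sc1, stages1)$rho
  }, numeric(1))
  expect_equal(sort(unique(rhos)), c(-1, -0.5, 0.5, 1))
})

test_that("hypergeometric moments and Z-score match the closed form", {
  u <- sprintf("g%03d", 1:100)
  res <- fisher_enrichment(u[1:10], u[6:15], u)
  expect_equal(res$k, 5)
  expect_equal(res$expected, 1.0)
  expect_equal(res$variance, 0.81818, tolerance = 1e-4)
  expect_equal(res$z_score, 4.42217, tolerance = 1e-3)

  # k equal to its expectation gives Z = 0
  res0 <- fisher_enrichment(u[1:10], u[10:19], u)
  expect_equal(res0$k, 1)
  expect_equal(res0$z_score, 0)

  # degenerate: gene set equals the universe
  resu <- fisher_enrichment(u[1:10], u, u)
  expect_equal(resu$p_value, 1)
  expect_true(is.na(resu$z_score))

  expect_error(fisher_enrichment(c("nope"), u[1:5], u), "subset")
})

test_that("Z-score sign agrees with enrichment direction", {
  withr::local_seed(34)
  u <- sprintf("g%03d", 1:60)
  for (i in 1:50) {
    hits <- sample(u, sample(5:20, 1))
    set <- sample(u, sample(5:20, 1))
    res <- fisher_enrichment(hits, set, u)
    if (!is.na(res$z_score) && res$z_score != 0)
      expect_equal(res$z_score > 0, res$k > res$expected)
  }
})

test_that("Fisher P matches exhaustive hypergeometric tail summation", {
  # two-sided P = sum of point probabilities no larger than the observed one
  exhaustive_p <- function(N, K, n, k) {
    ks <- max(0, n + K - N):min(n, K)
    pr <- stats::dhyper(ks, K, N - K, n)
    sum(pr[pr <= pr[ks == k] * (1 + 1e-7)])
  }
  withr::local_seed(35)
  for (i in 1:200) {
    N <- sample(4:50, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    klo <- max(0, n + K - N); khi <- min(n, K)
    k <- sample(klo:khi, 1)
    u <- sprintf("g%03d", 1:N)
    res <- fisher_enrichment(c(u[seq_len(k)], setdiff(u, u[seq_len(K)])[seq_len(n - k)]),
                             u[seq_len(K)], u)
    expect_equal(res$k, k)
    expect_equal(res$p_value, exhaustive_p(N, K, n, k), tolerance = 1e-10)
  }
})

test_that("top terms rank by Z then P then name, and truncate gracefully", {
  enr <- tibble::tibble(set_name = c("b_set", "a_set", "c_set"),
                        z_score = c(2, 2, 5), p_value = c(0.01, 0.01, 0.001),
                        q_value = c(0.015, 0.015, 0.003))
  top <- top_terms_report(enr, 10)
  expect_equal(top$set_name, c("c_set", "a_set", "b_set"))
  expect_equal(nrow(top_terms_report(enr, 2)), 2)
})

test_that("the planted age module ranks first for recovered age-sensitive genes", {
  cfg <- sim_config(n_genes = 150, seed = 36)
  sim <- simulate_dataset(cfg)
  res <- per_gene_age_correlation(sim$expression, sim$metadata, "brain")
  sel <- select_age_sensitive(res, "rho>0.7")
  universe <- res$gene_id[!is.na(res$rho_circ)]
  enr <- enrich_gene_sets(intersect(sel$gene_id, universe),
                          sim$gene_sets, universe)
  expect_equal(top_terms_report(enr, 1)$set_name, "age_up_module")
  expect_true(all(enr$q_value >= enr$p_value - 1e-12))
})
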