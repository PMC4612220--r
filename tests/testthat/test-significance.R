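test_that("null model pools and moments match hand computation", {
  hs <- make_hits(
    start_beta = c(10, 10, 200, 300), end_beta = c(60, 60, 250, 350),
    start_gamma = c(10, 100, 200, 300), end_gamma = c(60, 150, 250, 350),
    quality = c(0.2, 0.4, 0.6, 0.8),
    exon_beta = c("b1", "b1", "b2", "b3"),
    exon_gamma = c("g1", "g2", "g3", "g4"))
  null <- build_null_model(hs)
  expect_equal(length(null$pool_all), 4L)
  expect_equal(length(null$pool_best_beta), 3L)   # b1 twice -> best kept once
  expect_equal(length(null$pool_best_gamma), 4L)
  expect_equal(sort(null$pool_best_beta), c(0.4, 0.6, 0.8))
  expect_equal(null$moments$all$mean, mean(c(0.2, 0.4, 0.6, 0.8)))
  x <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(null$moments$all$var, mean((x - mean(x))^2))
  # degenerate: identical qualities give zero variance
  hs2 <- make_hits(c(1, 100), c(50, 150), c(1, 100), c(50, 150), quality = 0.5)
  expect_equal(build_null_model(hs2)$moments$all$var, 0)
})

test_that("permuted scores hit their degenerate identities and moment targets", {
  pool <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  null <- null_model(pool, c(0.4, 0.6), c(0.2, 0.8))
  set.seed(1)
  # exhaustive draw of the whole pool is constant
  s <- permuted_scores(null, n_c = 5, n_cbeta = 0, n_cgamma = 0, n_draws = 20)
  expect_true(all(s == 2 * sum(pool)))
  expect_true(all(permuted_scores(null, 0, 0, 0, 5) == 0))
  # mean of the permuted score matches its closed form within 3 SE
  set.seed(2)
  s <- permuted_scores(null, 2, 1, 1, 5000)
  mu <- 2 * 2 * mean(pool) - mean(c(0.4, 0.6)) - mean(c(0.2, 0.8))
  expect_lt(abs(mean(s) - mu), 3 * sd(s) / sqrt(length(s)))
})

test_that("permutation p-values agree with exhaustive enumeration on tiny pools", {
  pool_all <- c(0.15, 0.3, 0.45, 0.6, 0.75, 0.9)
  pool_b <- c(0.2, 0.5, 0.8)
  pool_g <- c(0.35, 0.65)
  null <- null_model(pool_all, pool_b, pool_g)
  cases <- list(list(n = 2, nb = 1, ng = 1), list(n = 3, nb = 2, ng = 0),
                list(n = 1, nb = 0, ng = 1))
  for (cs in cases) {
    for (q in c(0.25, 0.5, 0.75)) {
      # an observed score at the q-quantile of the exact null
      set.seed(99)
      probe <- permuted_scores(null, cs$n, cs$nb, cs$ng, 400)
      s_obs <- stats::quantile(probe, q, names = FALSE) + 1e-6
      exact <- enumerate_exact_p(pool_all, pool_b, pool_g,
                                 cs$n, cs$nb, cs$ng, s_obs)
      rec <- p_value_permutation(null, s_obs, cs$n, cs$nb, cs$ng,
                                 max_perms = 20000, early_stop_k = Inf,
                                 seed = 1234)
      se <- sqrt(exact * (1 - exact) / rec$n_draws)
      expect_lt(abs(rec$p_raw - exact), 3 * se + 2 / (rec$n_draws + 1))
    }
  }
})

test_that("extreme observed scores give the boundary p estimates", {
  null <- null_model(c(0.1, 0.2, 0.3, 0.4), c(0.1), c(0.1))
  # s_obs below any achievable score: every draw exceeds, early stop fires
  rec <- p_value_permutation(null, -10, 2, 0, 0, max_perms = 5000,
                             early_stop_k = 10, seed = 1)
  expect_true(rec$stopped)
  expect_gte(rec$n_exceed, 10)
  expect_lt(rec$n_draws, 5000)
  # s_obs above the max possible: zero exceedances, full budget
  rec2 <- p_value_permutation(null, 10, 2, 0, 0, max_perms = 999,
                              early_stop_k = 10, seed = 1)
  expect_equal(rec2$n_exceed, 0L)
  expect_equal(rec2$p_raw, 1 / 1000)
})

test_that("CLT p-values match the permutation engine on large pools", {
  set.seed(77)
  null <- null_model(runif(2000), runif(400), runif(400))
  n <- 60; nb <- 12; ng <- 12
  mu <- 2 * n * null$moments$all$mean - nb * null$moments$beta$mean -
    ng * null$moments$gamma$mean
  rec_mid <- p_value_clt(null, mu, n, nb, ng)
  expect_equal(rec_mid$p_raw, 0.5, tolerance = 1e-12)
  for (z in c(-2, 0, 2)) {
    s_obs <- mu + z * rec_mid$sd
    p_clt <- p_value_clt(null, s_obs, n, nb, ng)$p_raw
    rec <- p_value_permutation(null, s_obs, n, nb, ng, max_perms = 20000,
                               early_stop_k = Inf, seed = 5)
    expect_lt(abs(p_clt - rec$p_raw), 0.015)
  }
  # exhaustive draw of a pool contributes no variance
  null_small <- null_model(rep(0.5, 40), 0.3, 0.3)
  rec <- p_value_clt(null_small, 2 * 40 * 0.5 - 0.3, 40, 1, 0)
  expect_equal(rec$sd, 0)
  expect_error(p_value_clt(null, 1, 5, 0, 0), "too small")
})

test_that("the two-gene rule requires two genes on each organism", {
  fx <- synth_generate(synth_spec(
    seed = 61,
    blocks = list(list(beta_scaffold = 1, beta_genes = 3:6,
                       gamma_scaffold = 1, gamma_genes = 3:6)),
    n_noise = 0))
  forest <- build_forest(fx$hits)
  tree <- forest$trees[[1]]
  expect_true(passes_two_gene_rule(tree, tree$root, fx$beta, fx$gamma, fx$hits))
  # leaves touch one gene pair
  expect_false(passes_two_gene_rule(tree, 1, fx$beta, fx$gamma, fx$hits))
  # 2 beta genes vs 1 gamma gene fails the both-sides rule
  w_b <- make_annotation("beta", rbind(exon_row("bA.e1", "bA", "b1", 1, 60),
                                       exon_row("bB.e1", "bB", "b1", 200, 259)))
  w_g <- make_annotation("gamma", rbind(exon_row("gA.e1", "gA", "g1", 1, 60),
                                        exon_row("gA.e2", "gA", "g1", 200, 259)))
  hs <- make_hits(c(1, 200), c(60, 259), c(1, 200), c(60, 259),
                  exon_beta = c("bA.e1", "bB.e1"),
                  exon_gamma = c("gA.e1", "gA.e2"))
  t2 <- build_dendrogram(hs$hits)
  expect_false(passes_two_gene_rule(t2, t2$root, w_b, w_g, hs))
})

test_that("worst-case correction is twice the hit count and bounds the dynamic factor", {
  fx <- synth_generate(synth_spec(seed = 67, n_noise = 100))
  expect_equal(worst_case_correction(fx$hits), 200L)
  expect_equal(worst_case_correction(0L), 0L)
  res <- detect_synteny(fx$beta, fx$gamma, fx$hits, synteny_config(seed = 67))
  expect_lte(res$correction_factor, worst_case_correction(fx$hits))
})

test_that("a forest whose nodes all fail the two-gene rule yields no clusters", {
  # single gene pair: many hits but never two genes on both sides
  fx <- synth_generate(synth_spec(
    seed = 71, genes_per_scaffold = 1, n_scaffolds = c(beta = 1, gamma = 1),
    exons_per_gene = c(4, 6),
    blocks = list(list(beta_scaffold = 1, beta_genes = 1,
                       gamma_scaffold = 1, gamma_genes = 1)),
    n_noise = 5))
  res <- detect_synteny(fx$beta, fx$gamma, fx$hits, synteny_config(seed = 71))
  expect_equal(nrow(res$clusters), 0L)
  expect_equal(res$correction_factor, 0L)
})

test_that("the cut descends to a strictly better child", {
  # Two dense blocks far apart on both genomes plus nothing else: the root
  # joins them at a huge height with a sea of intervening unaccounted exons
  # (none penalized), while each block child is cleaner; children must win
  # if their p-values are strictly lower, else the parent is reported.
  fx <- synth_generate(synth_spec(
    seed = 73,
    blocks = list(list(beta_scaffold = 1, beta_genes = 2:7,
                       gamma_scaffold = 1, gamma_genes = 2:7),
                  list(beta_scaffold = 1, beta_genes = 13:18,
                       gamma_scaffold = 1, gamma_genes = 13:18)),
    n_noise = 150))
  res <- detect_synteny(fx$beta, fx$gamma, fx$hits, synteny_config(seed = 73))
  expect_gte(nrow(res$clusters), 1L)
  # every reported cluster is significant after correction and conserved
  expect_true(all(res$clusters$p_corrected <= 0.05 + 1e-12))
  expect_true(all(res$clusters$conservation_ratio >= 1))
  expect_true(all(res$clusters$n_genes_beta >= 2 & res$clusters$n_genes_gamma >= 2))
  # reported clusters are mutually non-nested within each tree
  for (k in unique(res$clusters$tree)) {
    rows <- res$clusters[res$clusters$tree == k, ]
    if (nrow(rows) > 1) {
      for (i in seq_len(nrow(rows) - 1)) {
        for (j in seq(i + 1, nrow(rows))) {
          a <- rows$hit_ids[[i]]; b <- rows$hit_ids[[j]]
          expect_equal(length(intersect(a, b)), 0L)
        }
      }
    }
  }
})

test_that("identical inputs and seed give identical cluster calls", {
  fx <- synth_generate(recovery_spec(83))
  cfg <- synteny_config(seed = 83)
  r1 <- detect_synteny(fx$beta, fx$gamma, fx$hits, cfg)
  r2 <- detect_synteny(fx$beta, fx$gamma, fx$hits, cfg)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$correction_factor, r2$correction_factor)
})
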