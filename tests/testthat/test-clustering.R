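test_that("region distance evaluates the gap formula", {
  expect_equal(region_distance(10, 20, 30, 40), 10)
  expect_equal(region_distance(30, 40, 10, 20), 10)
  expect_equal(region_distance(10, 25, 20, 40), 0)
  expect_equal(region_distance(10, 20, 10, 20), 0)
  expect_error(region_distance(1, 2, 3, 4, scaffold1 = "a", scaffold2 = "b"),
               "different scaffolds")
})

test_that("hit distance adds the per-genome region distances and is symmetric", {
  hs <- make_hits(start_beta = c(10, 30), end_beta = c(20, 40),
                  start_gamma = c(100, 90), end_gamma = c(120, 130))
  h1 <- hs$hits[1, ]; h2 <- hs$hits[2, ]
  expect_equal(hit_distance(h1, h2), 10 + 0)
  expect_equal(hit_distance(h1, h2), hit_distance(h2, h1))
  expect_equal(hit_distance(h1, h1), 0)
  h3 <- h2; h3$scaffold_gamma <- "g2"
  expect_error(hit_distance(h1, h3), "different scaffold pairs")
  # matrix form agrees with pairwise calls on random hits
  set.seed(42)
  s <- sample(1:500, 12); e <- s + sample(10:80, 12, TRUE)
  sg <- sample(1:500, 12); eg <- sg + sample(10:80, 12, TRUE)
  hs <- make_hits(s, e, sg, eg)
  D <- hit_distance_matrix(hs$hits)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(D[i, j], hit_distance(hs$hits[i, ], hs$hits[j, ]))
  }
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
})

test_that("three collinear hits chain at the expected heights", {
  # pairwise gaps 6, 6, 21: single linkage chains, so both merges sit at 6
  hs <- make_hits(start_beta = c(1, 16, 31), end_beta = c(10, 25, 40),
                  start_gamma = c(1, 1, 1), end_gamma = c(50, 50, 50))
  tree <- build_dendrogram(hs$hits)
  merges <- sort(tree$height[tree$child1 != 0])
  expect_equal(merges, c(6, 6))
  expect_equal(tree$n_hits[tree$root], 3L)
})

test_that("single leaf trees are valid", {
  hs <- make_hits(1, 10, 1, 10)
  tree <- build_dendrogram(hs$hits)
  expect_equal(tree$n_leaves, 1L)
  expect_equal(tree$height[tree$root], 0)
  expect_equal(tree$members[[tree$root]], 1L)
  expect_error(build_dendrogram(hs$hits[0, ]), "at least one")
})

test_that("merge heights and flat partitions match the brute-force single-linkage oracle", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    s <- sample(1:3000, n); e <- s + sample(5:200, n, TRUE)
    sg <- sample(1:3000, n); eg <- sg + sample(5:200, n, TRUE)
    hs <- make_hits(s, e, sg, eg)
    tree <- build_dendrogram(hs$hits)
    D <- hit_distance_matrix(hs$hits)
    expect_equal(sort(tree$height[tree$child1 != 0]),
                 naive_single_linkage_heights(D))
    for (h in unique(c(0, tree$height))) {
      expect_equal(clusters_at_height(tree, h), components_at_height(D, h))
    }
  }
})

test_that("the tree is invariant to input order up to leaf numbering", {
  set.seed(7)
  n <- 30
  s <- sample(1:2000, n); e <- s + sample(5:150, n, TRUE)
  sg <- sample(1:2000, n); eg <- sg + sample(5:150, n, TRUE)
  hs <- make_hits(s, e, sg, eg)
  perm <- sample(n)
  hs_perm <- hit_set(hs$hits[perm, ])   # same hit_ids, shuffled rows
  t1 <- build_dendrogram(hs$hits)
  t2 <- build_dendrogram(hs_perm$hits)
  expect_equal(sort(t1$height[t1$child1 != 0]), sort(t2$height[t2$child1 != 0]))
  for (h in unique(t1$height)) {
    expect_equal(clusters_at_height(t1, h), clusters_at_height(t2, h))
  }
})

test_that("heights are monotone along every rootward path", {
  fx <- synth_generate(synth_spec(seed = 41, n_noise = 120))
  forest <- build_forest(fx$hits)
  for (tree in forest$trees) {
    internal <- which(tree$child1 != 0)
    for (v in internal) {
      expect_gte(tree$height[v], tree$height[tree$child1[v]])
      expect_gte(tree$height[v], tree$height[tree$child2[v]])
    }
  }
})

test_that("the forest buckets hits by scaffold pair and conserves leaves", {
  fx <- synth_generate(synth_spec(seed = 43, n_noise = 80))
  forest <- build_forest(fx$hits)
  expect_equal(sum(vapply(forest$trees, function(t) t$n_leaves, 0L)),
               nrow(fx$hits$hits))
  all_leaf_ids <- sort(unname(unlist(lapply(forest$trees, `[[`, "leaf_hit_ids"))))
  expect_equal(all_leaf_ids, sort(fx$hits$hits$hit_id))
  # every tree's hits share one scaffold pair
  for (k in names(forest$trees)) {
    t <- forest$trees[[k]]
    expect_equal(k, paste(t$scaffold_beta, t$scaffold_gamma, sep = "|"))
  }
})

test_that("newick export parses as a valid tree with matching leaf count", {
  hs <- make_hits(start_beta = c(1, 16, 31), end_beta = c(10, 25, 40),
                  start_gamma = c(1, 1, 1), end_gamma = c(50, 50, 50))
  tree <- build_dendrogram(hs$hits)
  nw <- as_newick(tree)
  expect_match(nw, ";$")
  expect_equal(lengths(regmatches(nw, gregexpr("h[0-9]+", nw))), 3L)
})
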