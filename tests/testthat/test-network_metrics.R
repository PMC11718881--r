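test_that("node strength sums incident weights", {
  ai <- load_fixture("ai")
  s <- node_strength(ai)
  expect_equal(s[["Lovelas"]], 0.665)
  expect_equal(unname(s), unname(rowSums(dyad_values(ai))))
  af <- load_fixture("affil_rates")
  expect_equal(node_strength(af, "total")[["Vernij"]], 0.046)
  expect_equal(node_strength(af, "out")[["Vernij"]], 0)
  z <- dyad_matrix(matrix(0, 3, 3), ids = letters[1:3])
  expect_true(all(node_strength(z) == 0))
})

test_that("weighted degree interpolates between tie count and strength", {
  ai <- load_fixture("ai")
  v <- dyad_values(ai)
  k <- rowSums(v > 0)
  S <- rowSums(v)
  expect_equal(weighted_degree(ai, alpha = 0), k)
  expect_equal(weighted_degree(ai, alpha = 1), S)
  expect_equal(weighted_degree(ai, alpha = 0.5), sqrt(k * S))
  # monotone in alpha for every node
  grid <- seq(0, 1, by = 0.1)
  for (id in c("Lovelas", "Bulat", "Zakat")) {
    path <- vapply(grid, function(a) weighted_degree(ai, a)[[id]],
                   numeric(1))
    expect_true(all(diff(path) <= 1e-9) || all(diff(path) >= -1e-9))
  }
  # directed: zero outgoing ties -> 0 despite incoming strength
  af <- load_fixture("affil_rates")
  expect_equal(weighted_degree(af, 0.5)[["Vernij"]], 0)
  expect_equal(round(weighted_degree(af, 0.5)[["Lovelas"]], 3), 0.214)
  expect_error(weighted_degree(ai, 1.2), "alpha")
})

test_that("modularity matches its closed form and igraph", {
  ai <- load_fixture("ai")
  ids <- dyad_ids(ai)
  # trivial partition normalizes to zero
  expect_equal(modularity_q(ai, setNames(rep(1, 9), ids)), 0)
  part <- bachelor_partition()
  q <- modularity_q(ai, part)
  g <- igraph::graph_from_adjacency_matrix(dyad_values(ai),
                                           mode = "undirected",
                                           weighted = TRUE)
  expect_equal(q, igraph::modularity(g, part$membership[ids],
                                     weights = igraph::E(g)$weight))
  # two disconnected cliques: hand-derived Q = 1/2 for equal halves
  v <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  v[1:3, 1:3] <- 1; v[4:6, 4:6] <- 1; diag(v) <- 0
  m2 <- dyad_matrix(v)
  expect_equal(modularity_q(m2, setNames(rep(1:2, each = 3), letters[1:6])),
               0.5)
  expect_error(modularity_q(dyad_matrix(matrix(0, 2, 2), ids = c("a", "b")),
                            c(1, 2)), "zero-weight")
})

test_that("community detection recovers separated cliques", {
  v <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  v[1:3, 1:3] <- 1; v[4:7, 4:7] <- 1; diag(v) <- 0
  part <- detect_communities(dyad_matrix(v), seed = 1, n_restart = 10)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:3])), 1)
  expect_equal(length(unique(part$membership[4:7])), 1)
  expect_equal(part$modularity,
               modularity_q(dyad_matrix(v), part$membership))
  # complete uniform graph: no structure, single community, Q ~ 0
  u <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(u) <- 0
  pu <- detect_communities(dyad_matrix(u), seed = 1, n_restart = 10)
  expect_equal(length(unique(pu$membership)), 1)
  expect_lt(abs(pu$modularity), 1e-9)
  # detected Q beats a random partition of a planted-cluster graph
  g <- synth_generate(synth_config(days = 3, scans_per_day = 10, seed = 6))
  ai <- association_matrix(g$scans)
  det <- detect_communities(ai, seed = 6, n_restart = 10)
  set.seed(1)
  rnd <- setNames(sample(1:3, 9, replace = TRUE), dyad_ids(ai))
  expect_gt(det$modularity, modularity_q(ai, rnd))
})

test_that("modularity p-value behaves at the permutation-count extremes", {
  g <- synth_generate(synth_config(days = 5, scans_per_day = 10, seed = 9))
  ai <- association_matrix(g$scans)
  part <- detect_communities(ai, seed = 9, n_restart = 10)
  r1 <- partition_pvalue(ai, part, n_perm = 1, seed = 1, n_restart = 2)
  expect_true(r1$p_value %in% c(0, 1))
  r <- partition_pvalue(ai, part, n_perm = 49, seed = 1, n_restart = 3)
  expect_lte(r$p_value, 0.05)
})

test_that("assortment is 1 for perfectly assorted cliques and trait-affine", {
  v <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  v[1:3, 1:3] <- 1; v[4:6, 4:6] <- 1; diag(v) <- 0
  m <- dyad_matrix(v)
  trait <- setNames(c(1, 1, 1, 5, 5, 5), letters[1:6])
  expect_equal(assortment_continuous(m, trait, n_node_perm = 0)$ac, 1)
  ai <- load_fixture("ai")
  nm <- load_fixture("node_measures")
  tr <- setNames(nm$wd_assoc, nm$id)
  a1 <- assortment_continuous(ai, tr, n_node_perm = 0)$ac
  a2 <- assortment_continuous(ai, 2 * tr + 3, n_node_perm = 0)$ac
  expect_equal(a1, a2)
  expect_error(assortment_continuous(m, setNames(rep(1, 6), letters[1:6]),
                                     n_node_perm = 0), "constant trait")
})

test_that("adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand(c(a = 1, b = 1, c = 2), c(a = 2, b = 2, c = 1)), 1)
  set.seed(7)
  for (k in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
  }
})
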