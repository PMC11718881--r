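test_that("CV statistic matches direct arithmetic", {
  # constant off-diagonal values -> CV 0
  m <- dyad_matrix(matrix(0.3, 3, 3), ids = c("a", "b", "c"))
  expect_equal(cv_statistic(m), 0)
  # directed 2x2 with ordered values {0, x}: sd = x/sqrt(2), mean = x/2
  d <- dyad_matrix(matrix(c(0, 0, 0.4, 0), 2), directed = TRUE,
                   ids = c("a", "b"))
  expect_equal(cv_statistic(d), sqrt(2))
  z <- dyad_matrix(matrix(0, 3, 3), ids = c("a", "b", "c"))
  expect_error(cv_statistic(z), "zero mean")
})

test_that("swap chain conserves group sizes and daily observation counts", {
  # partial visibility: drop one individual from some scans to open
  # cross-scan swaps too
  g <- synth_generate(synth_config(days = 2, scans_per_day = 6, seed = 13))
  sc <- g$scans$scans
  drop <- sc$individual == "ind01" & sc$time %in% c(300, 320)
  pr <- g$scans$pairs
  pr <- pr[!((pr$id_a == "ind01" | pr$id_b == "ind01") &
               pr$time %in% c(300, 320)), ]
  x <- scan_dataset(sc[!drop, ], pr, ids = g$scans$ids)
  st <- herdnet:::swap_state(x)
  sizes0 <- lapply(split(lengths(st$groups), st$gscan), sort)
  day_of_scan <- st$gday[!duplicated(st$gscan)]
  daily0 <- t(rowsum(t(st$pres), day_of_scan))
  set.seed(4)
  moved_across <- FALSE
  for (k in 1:300) {
    ok <- herdnet:::try_swap(st)
    if (is.null(ok)) next
    if (!identical(ok$pres, st$pres)) moved_across <- TRUE
    st <- ok
  }
  expect_identical(lapply(split(lengths(st$groups), st$gscan), sort), sizes0)
  expect_identical(t(rowsum(t(st$pres), day_of_scan)), daily0)
  expect_true(all(st$pres %in% c(0L, 1L)))
  # and the incremental tallies still match a from-scratch rebuild
  num2 <- matrix(0L, st$n, st$n)
  for (gi in seq_along(st$groups)) {
    mem <- st$groups[[gi]]
    num2[mem, mem] <- num2[mem, mem] + 1L
  }
  diag(num2) <- 0L
  expect_identical(st$num, num2)
})

test_that("permutation chains are reproducible and id-order invariant", {
  g <- synth_generate(synth_config(days = 2, scans_per_day = 8, seed = 3))
  r1 <- datastream_permute(g$scans, n_perm = 50, seed = 17)
  r2 <- datastream_permute(g$scans, n_perm = 50, seed = 17)
  expect_identical(r1$null_stats, r2$null_stats)
  # reordering the id universe must not change the statistic chain
  x2 <- scan_dataset(g$scans$scans, g$scans$pairs,
                     ids = rev(g$scans$ids))
  r3 <- datastream_permute(x2, n_perm = 50, seed = 17)
  expect_equal(r1$null_stats, r3$null_stats)
  expect_equal(r1$p_value, r3$p_value)
})

test_that("a stream with a single all-animal group is degenerate", {
  x <- toy_scans(rep_days(list(list(c("A", "B", "C"))), 2))
  expect_error(datastream_permute(x, n_perm = 10, seed = 1), "degenerate")
})

test_that("planted structure is detected as non-random association", {
  g <- synth_generate(synth_config(days = 11, seed = 31))
  r <- datastream_permute(g$scans, n_perm = 500, seed = 31)
  expect_lt(r$p_value, 0.01)
})

test_that("dyad classification recovers planted and missing bonds", {
  g <- synth_generate(synth_config(
    n_individuals = 9, cluster_sizes = c(2, 7), p_within = 0.9,
    p_between = 0, days = 4, scans_per_day = 12, seed = 19))
  cl <- classify_dyads(g$scans, n_perm = 200, thin = 10, seed = 19)
  expect_equal(cl$label["ind01", "ind02"], "preferred")
  # never-associated dyad against a dense background
  expect_equal(cl$label["ind01", "ind05"], "avoided")
  expect_true(all(cl$dyads$label %in% c("preferred", "avoided", "neutral")))
})

test_that("Mantel correlation matches enumeration and vegan", {
  ai <- load_fixture("ai")
  self <- mantel_test(ai, ai, n_perm = 50, seed = 1)
  expect_equal(self$observed_stat, 1)
  # 4x4 toy: exhaustive p equals an independently coded enumeration
  set.seed(42)
  va <- matrix(0, 4, 4); va[upper.tri(va)] <- runif(6)
  va <- va + t(va)
  vb <- matrix(0, 4, 4); vb[upper.tri(vb)] <- runif(6)
  vb <- vb + t(vb)
  a <- dyad_matrix(va, ids = letters[1:4])
  b <- dyad_matrix(vb, ids = letters[1:4])
  res <- mantel_test(a, b, exhaustive = TRUE, alternative = "greater")
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  stats <- apply(perms, 1, function(p) {
    bp <- vb[p, p]
    cor(va[upper.tri(va)], bp[upper.tri(bp)])
  })
  expect_equal(length(stats), 24)
  expect_equal(sort(res$null_stats), sort(stats))
  expect_equal(res$p_value, mean(stats >= res$observed_stat))
  # observed statistic agrees with vegan's Mantel
  skip_if_not_installed("vegan")
  bsi <- load_fixture("bsi")
  vres <- vegan::mantel(as.dist(dyad_values(ai)), as.dist(dyad_values(bsi)),
                        permutations = 99)
  ours <- mantel_test(ai, bsi, n_perm = 99, seed = 3,
                      alternative = "greater")
  expect_equal(ours$observed_stat, unname(vres$statistic))
  expect_error(mantel_test(a, dyad_matrix(matrix(0.2, 4, 4),
                                          ids = letters[1:4])),
               "constant matrix")
})

test_that("directed matrices symmetrize by summing directions", {
  af <- load_fixture("affil_rates")
  s <- symmetrize(af)
  expect_false(is_directed(s))
  expect_equal(dyad_values(s)["Losk", "Zakat"], 1.077 + 0.077)
  expect_error(mantel_test(af, af), "symmetrize")
})
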