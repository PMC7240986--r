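test_that("pair weights follow the half-sum-of-reciprocals formula", {
  pairs <- data.frame(gene1 = c("A", "A"), gene2 = c("B", "C"))
  w <- pair_weights(pairs)
  expect_equal(w, c(0.75, 0.75))  # A appears twice, partners once

  pairs1 <- data.frame(gene1 = c("A", "C"), gene2 = c("B", "D"))
  expect_equal(pair_weights(pairs1), c(1, 1))

  hub <- data.frame(gene1 = rep("A", 4), gene2 = rep("B", 4))
  expect_equal(pair_weights(hub), rep(0.25, 4))
})

test_that("weighted Spearman with equal weights equals ordinary Spearman", {
  expect_equal(weighted_spearman(c(1, 2, 3), c(3, 2, 1), B = 0)$rho_s, -1)
  set.seed(14)
  for (i in 1:25) {
    m <- sample(5:40, 1)
    x <- rnorm(m); y <- rnorm(m)
    if (i %% 3 == 0) x <- round(x)  # exercise ties
    expect_equal(weighted_spearman(x, y, B = 0)$rho_s,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("weighted Spearman matches a weighted-Pearson-on-ranks oracle", {
  set.seed(15)
  for (i in 1:10) {
    m <- sample(4:20, 1)
    x <- rnorm(m); y <- rnorm(m)
    w <- c(rep(1, m - 1), 0.01)
    got <- weighted_spearman(x, y, weights = w, B = 0)$rho_s
    oracle <- cov.wt(cbind(rank(x), rank(y)), wt = w, cor = TRUE)$cor[1, 2]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # worked example
  got <- weighted_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4),
                           weights = c(1, 1, 1, 0.01), B = 0)$rho_s
  oracle <- cov.wt(cbind(1:4, c(1, 3, 2, 4)), wt = c(1, 1, 1, 0.01),
                   cor = TRUE)$cor[1, 2]
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("bootstrap CI brackets the estimate and the p-value is sane", {
  set.seed(16)
  for (i in 1:10) {
    m <- sample(10:30, 1)
    x <- rnorm(m); y <- x + rnorm(m, sd = 0.8)
    res <- weighted_spearman(x, y, B = 300, seed = i)
    expect_lte(res$ci[1], res$rho_s)
    expect_gte(res$ci[2], res$rho_s)
    expect_gt(res$p, 0)
    expect_lte(res$p, 1)
  }
  # recomputing weights per resample from appearance counts is deterministic
  pairs <- data.frame(gene1 = c("A", "A", "B", "C"),
                      gene2 = c("B", "C", "D", "E"))
  r1 <- weighted_spearman(1:4, c(2, 1, 4, 3), pairs = pairs, B = 200, seed = 7)
  r2 <- weighted_spearman(1:4, c(2, 1, 4, 3), pairs = pairs, B = 200, seed = 7)
  expect_equal(r1, r2)
})

test_that("group tests report one-sample CIs and the Welch comparison", {
  set.seed(17)
  b <- rnorm(50, 0.45, 0.1); ctrl <- rnorm(50, 0.02, 0.1)
  gt <- group_tests(b, ctrl)
  expect_equal(gt$binding$mean, mean(b))
  tt <- t.test(b, mu = 0)
  expect_equal(gt$binding$ci, unname(tt$conf.int))
  expect_equal(gt$welch$p, t.test(b, ctrl)$p.value)
  expect_error(group_tests(c(0.4, 0.5), c(0, 0)), "zero variance")
  expect_error(group_tests(rep(1, 4), rep(-1, 4)), "zero variance")
})

test_that("BH adjustment reproduces the worked example and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  set.seed(18)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_lte(max(q), 1)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("membership subsets keep each gene in at most one pair", {
  # disjoint pairs: every subset is the full set
  pairs <- data.frame(gene1 = paste0("a", 1:5), gene2 = paste0("b", 1:5))
  ms <- membership_subsets(pairs, n_subsets = 10, max_size = 200, seed = 1)
  expect_true(all(vapply(ms$subsets, length, 1L) == 5))

  # hub gene: every subset has exactly one pair
  hub <- data.frame(gene1 = rep("hub", 6), gene2 = paste0("x", 1:6))
  ms2 <- membership_subsets(hub, n_subsets = 10, seed = 2)
  expect_true(all(vapply(ms2$subsets, length, 1L) == 1))

  # no gene repeated within a subset; max_size respected; seeded determinism
  set.seed(3)
  big <- data.frame(gene1 = sample(paste0("g", 1:40), 60, replace = TRUE),
                    gene2 = sample(paste0("h", 1:40), 60, replace = TRUE))
  vals <- data.frame(rho_c = rnorm(60))
  m1 <- membership_subsets(big, vals, n_subsets = 20, max_size = 10, seed = 4)
  m2 <- membership_subsets(big, vals, n_subsets = 20, max_size = 10, seed = 4)
  expect_equal(m1, m2)
  for (idx in m1$subsets) {
    g <- c(big$gene1[idx], big$gene2[idx])
    expect_equal(anyDuplicated(g), 0)
    expect_lte(length(idx), 10)
  }
  expect_equal(nrow(m1$means), 20)
})
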