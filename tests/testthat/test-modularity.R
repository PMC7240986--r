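triangle <- function(nodes, w = 1) {
  data.frame(gene1 = nodes[c(1, 1, 2)], gene2 = nodes[c(2, 3, 3)], weight = w)
}

clique <- function(nodes, w = 1) {
  idx <- t(combn(length(nodes), 2))
  data.frame(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]], weight = w)
}

test_that("MCL separates disconnected components and trivial graphs", {
  net <- rbind(triangle(c("a1", "a2", "a3")), triangle(c("b1", "b2", "b3")))
  mod <- mcl(net)
  expect_length(unique(mod), 2)
  expect_length(unique(mod[c("a1", "a2", "a3")]), 1)
  expect_length(unique(mod[c("b1", "b2", "b3")]), 1)

  single <- data.frame(gene1 = "A", gene2 = "B", weight = 0.7)
  expect_equal(unname(mcl(single)), c(1L, 1L))
})

test_that("MCL splits two cliques joined by a weak bridge", {
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  net <- rbind(clique(a), clique(b),
               data.frame(gene1 = "a1", gene2 = "b1", weight = 0.01))
  mod <- mcl(net, inflation = 2)
  expect_length(unique(mod), 2)
  expect_length(unique(mod[a]), 1)
  expect_length(unique(mod[b]), 1)
  # deterministic
  expect_equal(mod, mcl(net, inflation = 2))
})

test_that("network coercion rejects self-loops and bad weights", {
  expect_error(as_weighted_network(
    data.frame(gene1 = "A", gene2 = "A", weight = 1)), "self-loops")
  expect_error(as_weighted_network(
    data.frame(gene1 = "A", gene2 = "B", weight = 0)), "positive")
})

test_that("phylo_transform centers and rescales star-tree data", {
  t0 <- 4
  C <- star_C(6, t = t0)
  X <- matrix(rnorm(18), 6, 3)
  Xt <- phylo_transform(X, C)
  # the transform is defined up to row rotation/permutation (eigenvector
  # order); compare the rotation-invariant cross-products
  Xc <- scale(X, scale = FALSE)
  expect_equal(crossprod(Xt), crossprod(Xc) / t0,
               tolerance = 1e-10, ignore_attr = TRUE)
  # constant trait -> all zeros after GLS centering
  Xt1 <- phylo_transform(matrix(3, 6, 1), C)
  expect_equal(unname(Xt1), matrix(0, 6, 1))
})

test_that("transformed rows recover the evolutionary covariance", {
  set.seed(33)
  tr <- simulate_tree(8, root_age = 5)
  C <- tree_vcv(tr)
  R <- rate_matrix(1, 2, 0.6)
  S_acc <- matrix(0, 2, 2)
  nrep <- 300
  for (i in seq_len(nrep)) {
    X <- t(simulate_pair(C = C, R = R))
    Xt <- phylo_transform(X, C)
    # one df absorbed by the GLS root estimate
    S_acc <- S_acc + crossprod(Xt) / (nrow(Xt) - 1)
  }
  expect_equal(unname(S_acc / nrep), R, tolerance = 0.1)
})

test_that("covariance ratio is zero for exactly orthogonal blocks", {
  # centered block patterns with zero cross-covariance by construction
  v <- c(1, -1, 1, -1, 1, -1, 1, -1)
  w <- c(1, 1, -1, -1, 1, 1, -1, -1)
  X <- cbind(v, 2 * v, w, -w)
  colnames(X) <- c("t1", "t2", "t3", "t4")
  modules <- setNames(c(1, 1, 2, 2), colnames(X))
  res <- covariance_ratio(X, modules, n_perm = 99, min_size = 2, seed = 1)
  expect_equal(res$cr, 0, tolerance = 1e-12)
})

test_that("covariance ratio is invariant to within-module reordering and scaling", {
  set.seed(34)
  X <- matrix(rnorm(12 * 8), 12, 8)
  colnames(X) <- paste0("t", 1:8)
  modules <- setNames(rep(1:2, each = 4), colnames(X))
  base <- covariance_ratio(X, modules, n_perm = 0, min_size = 2)
  perm_within <- c(sample(1:4), sample(5:8))
  reord <- covariance_ratio(X[, perm_within], modules[perm_within],
                            n_perm = 0, min_size = 2)
  expect_equal(reord$cr, base$cr, tolerance = 1e-12)
  scaled <- covariance_ratio(X * 7.3, modules, n_perm = 0, min_size = 2)
  expect_equal(scaled$cr, base$cr, tolerance = 1e-12)
})

test_that("planted modular structure yields CR < 1 with small p", {
  set.seed(35)
  n <- 18; k <- 10
  rho <- 0.9
  blk <- matrix(rho, k / 2, k / 2); diag(blk) <- 1
  S <- rbind(cbind(blk, matrix(0, k / 2, k / 2)),
             cbind(matrix(0, k / 2, k / 2), blk))
  L <- chol(S)
  X <- matrix(rnorm(n * k), n, k) %*% L
  colnames(X) <- paste0("t", 1:k)
  modules <- setNames(rep(1:2, each = k / 2), colnames(X))
  res <- covariance_ratio(X, modules, n_perm = 199, min_size = 2, seed = 2)
  expect_lt(res$cr, 1)
  expect_lte(res$p_value, 0.05)
})

test_that("degenerate module structures are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  colnames(X) <- paste0("t", 1:4)
  expect_error(covariance_ratio(X, setNames(rep(1, 4), colnames(X)),
                                min_size = 2), "at least 2 modules")
  expect_error(covariance_ratio(X, setNames(c(1, 1, 1, 2), colnames(X)),
                                min_size = 2), "at least 2 modules")
})
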