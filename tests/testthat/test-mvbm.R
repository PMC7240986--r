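test_that("loglik matches the closed-form univariate star-tree value", {
  # star tree, 3 tips of depth 1, x = (1, 0, -1), theta = 0, sigma2 = 2/3;
  # the second trait contributes only its own normalizing constant
  C <- star_C(3)
  x <- rbind(c(1, 0, -1), c(0, 0, 0))
  ll <- mvbm_loglik(C, x, theta = c(0, 0), R = diag(2 / 3, 2))
  l2 <- -(3 / 2) * log(2 * pi * 2 / 3)
  expect_equal(ll - l2, -3.6486, tolerance = 1e-4)
})

test_that("loglik agrees with the dense MVN oracle on random instances", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    C <- tree_vcv(simulate_tree(n, root_age = runif(1, 0.5, 10)))
    R <- random_rate_matrix()
    se <- matrix(runif(2 * n, 0, 0.5), 2, n)
    theta <- rnorm(2)
    x <- simulate_pair(C = C, R = R, theta = theta, se = se)
    expect_equal(mvbm_loglik(C, x, se, theta, R),
                 oracle_mvbm_loglik(C, x, se, theta, R), tolerance = 1e-8)
  }
})

test_that("huge measurement error on one species approaches the pruned fit", {
  set.seed(5)
  tr <- simulate_tree(10, root_age = 50)
  C <- tree_vcv(tr)
  X <- simulate_pair(C = C, R = rate_matrix(1, 1, 0.6))
  se_x <- rep(0, 10); se_x[3] <- 1e6
  f_noisy <- bm_corr(X[1, ], X[2, ], C = C, se_x = se_x, se_y = se_x)
  pruned <- prune_tree(tr, colnames(C)[-3])
  Cp <- tree_vcv(pruned)
  f_pruned <- bm_corr(X[1, colnames(Cp)], X[2, colnames(Cp)], C = Cp)
  expect_equal(f_noisy$rho_c, f_pruned$rho_c, tolerance = 1e-3)
})

test_that("on a star tree rho_C equals the Pearson correlation", {
  C <- star_C(4)
  f <- bm_corr(c(1, 2, 3, 4), c(1, 3, 2, 4), C = C)
  expect_equal(f$rho_c, 0.8, tolerance = 1e-5)
  expect_equal(f$rho_u, 0.8, tolerance = 1e-12)
  # and the LRT reduces to the bivariate-normal closed form -n log(1 - r^2)
  expect_equal(f$lrt, -4 * log(1 - 0.8^2), tolerance = 1e-5)

  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    f <- bm_corr(x, y, C = star_C(n, t = runif(1, 0.5, 4)))
    expect_lt(abs(f$rho_c - cor(x, y)), 1e-5)
    expect_lt(abs(f$lrt - (-n * log(1 - cor(x, y)^2))), 1e-4)
  }
})

test_that("the constrained fit forces r12 = 0 and the LRT is floored at 0", {
  f <- bm_corr(c(1, 2, 3, 4), c(1, 3, 2, 4), C = star_C(4))
  expect_equal(f$null$R[1, 2], 0)
  expect_equal(f$null$rho_c, 0)
  expect_gte(f$lrt, 0)
  expect_equal(f$p_value, pchisq(f$lrt, 1, lower.tail = FALSE))
})

test_that("collinear traits hit the correlation boundary and are flagged", {
  x <- c(1, 2, 3, 5, 4)
  f <- bm_corr(x, x, C = star_C(5))
  expect_true(f$full$boundary)
  expect_equal(abs(f$rho_c), 1 - 1e-6)
})

test_that("the LRT is invariant to affine rescaling of either trait", {
  set.seed(31)
  C <- tree_vcv(simulate_tree(12, root_age = 30))
  X <- simulate_pair(C = C, R = rate_matrix(1, 2, 0.5))
  f1 <- bm_corr(X[1, ], X[2, ], C = C)
  f2 <- bm_corr(5 * X[1, ] - 3, X[2, ] / 7 + 2, C = C)
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-5)
  expect_equal(f1$rho_c, f2$rho_c, tolerance = 1e-5)
})

test_that("rho_u reproduces cor.test and rejects degenerate input", {
  r <- rho_u(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  expect_equal(rho_u(1:5, -(1:5))$r, -1)
  expect_error(rho_u(1:5, rep(2, 5)), "non-constant")
  expect_error(rho_u(1:2, 2:1), "at least 3")
})

test_that("bm_corr input validation catches bad shapes and degenerate traits", {
  C <- star_C(4)
  expect_error(bm_corr(1:4, rep(1, 4), C = C), "non-constant")
  expect_error(bm_corr(1:3, 1:3, C = C), "length must match")
  expect_error(bm_corr(c(1, 2), c(2, 1), C = star_C(2)), "at least 3")
  expect_warning(bm_corr(c(1, 2, 3, 4), c(1, 3, 2, 4), C = C,
                         se_x = c(NA, 0, 0, 0)), "missing SE")
})

test_that("bm_corr methods expose coefficients, simulations and residuals", {
  set.seed(12)
  tr <- simulate_tree(8, root_age = 10)
  X <- simulate_pair(tree = tr, R = rate_matrix(1, 1, 0.5))
  f <- bm_corr(X[1, ], X[2, ], tree = tr)
  co <- coef(f)
  expect_equal(unname(co["rho_c"]),
               unname(co["r12"] / sqrt(co["r11"] * co["r22"])),
               tolerance = 1e-10)
  expect_equal(as.numeric(logLik(f)), f$full$loglik)
  s1 <- simulate(f, seed = 99)
  s2 <- simulate(f, seed = 99)
  expect_equal(s1, s2)
  expect_equal(dim(s1), c(2L, 8L))
  res <- residuals(f)
  expect_equal(dim(res), c(2L, 8L))
  expect_output(print(f), "rho_C")
  expect_output(summary(f), "rate matrix")
})

test_that("fit_pairs returns per-pair estimates with BH-adjusted q-values", {
  cfg <- sim_config(n_binding = 8, n_control = 8, seed = 42)
  sim <- generate_pair_sets(cfg)
  fits <- fit_pairs(sim$panel, sim$pairs, sim$tree)
  expect_s3_class(fits, "phycor_fits")
  expect_equal(nrow(fits), 16)
  expect_true(all(c("rho_c", "rho_u", "lrt", "p", "q", "q_u") %in% names(fits)))
  ok <- fits$converged
  expect_equal(fits$q[ok], bh_adjust(fits$p[ok]))
  expect_true(all(abs(fits$rho_c) <= 1))
  expect_true(all(fits$lrt[ok] >= 0))
  # rho_c = r12 / sqrt(r11 r22) by construction
  expect_equal(fits$rho_c[ok],
               (fits$r12 / sqrt(fits$r11 * fits$r22))[ok], tolerance = 1e-6)
})
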