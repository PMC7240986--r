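# Shared fixtures and independent oracles for the test suite.

# Write a Newick string to a temp file and read it back through the package.
read_newick_text <- function(text) {
  f <- tempfile(fileext = ".nwk")
  writeLines(text, f)
  read_newick(f)
}

# Star-tree species covariance of depth t (labels A, B, C, ...).
star_C <- function(n, t = 1) {
  C <- diag(t, n)
  dimnames(C) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  C
}

# Independent dense multivariate-normal log-density oracle for the bivariate
# Brownian-Motion model: builds the full 2n x 2n covariance and evaluates the
# density through an eigendecomposition (a different linear-algebra route
# than the implementation's Cholesky factorization).
oracle_mvbm_loglik <- function(C, x, se, theta, R) {
  n <- ncol(C)
  Sigma <- kronecker(R, C) + diag(c(se[1, ]^2, se[2, ]^2), 2 * n)
  y <- c(x[1, ], x[2, ]) - rep(theta, each = n)
  eg <- eigen(Sigma, symmetric = TRUE)
  w <- t(eg$vectors) %*% y
  -0.5 * (2 * n * log(2 * pi) + sum(log(eg$values)) + sum(w^2 / eg$values))
}

# A random PD 2x2 rate matrix.
random_rate_matrix <- function() {
  rate_matrix(exp(stats::rnorm(1)), exp(stats::rnorm(1)),
              stats::runif(1, -0.9, 0.9))
}
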