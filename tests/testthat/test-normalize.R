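test_that("standardize_sample maps TPM to standard lognormal scale", {
  z <- standardize_sample(c(1, exp(1), exp(2)))
  expect_equal(z, c(-1, 0, 1))
  expect_error(standardize_sample(c(5, 5, 5)), "zero variance")
  z2 <- standardize_sample(c(0, 1, exp(1), exp(2)))
  expect_true(is.na(z2[1]))
  expect_equal(z2[-1], c(-1, 0, 1))
  expect_error(standardize_sample(c(0, 0, 0)), "at least 3")
  expect_error(standardize_sample(c(-1, 2, 3)), "nonnegative")
})

test_that("standardized samples have mean 0 and sd 1 over observed genes", {
  set.seed(11)
  for (i in 1:20) {
    tpm <- rlnorm(50, meanlog = runif(1, 0, 4), sdlog = runif(1, 0.5, 2))
    tpm[sample(50, 5)] <- 0
    z <- standardize_sample(tpm)
    expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-9)
    expect_equal(sd(z[!is.na(z)]), 1, tolerance = 1e-9)
  }
})

test_that("summarize_replicates computes means and standard errors", {
  s <- summarize_replicates(matrix(c(-1, 0, 1), 1, 3))
  expect_equal(s$mean, 0)
  expect_equal(s$se, 1 / sqrt(3))
  s1 <- summarize_replicates(matrix(2.5, 1, 1))
  expect_equal(s1$mean, 2.5)
  expect_true(is.na(s1$se))
  s2 <- summarize_replicates(matrix(2, 1, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$se, 0)
  expect_error(summarize_replicates(list()), "no replicates")
})

test_that("standard error scales as 1/sqrt(m) on replicated noise", {
  set.seed(3)
  ses <- sapply(c(4, 16, 64), function(m) {
    mean(replicate(300, summarize_replicates(matrix(rnorm(m), 1, m))$se))
  })
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.1)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.1)
})

make_panel <- function(mean_m, se_m) {
  phycor:::new_expression_panel(rownames(mean_m), colnames(mean_m),
                                mean_m, se_m,
                                setNames(rep(3L, nrow(mean_m)),
                                         rownames(mean_m)))
}

test_that("apply_proxy_se inherits SEs gene-wise from the proxy species", {
  m <- matrix(0, 3, 2, dimnames = list(c("P", "Q", "R"), c("g1", "g2")))
  se <- m
  se["P", ] <- NA
  se["Q", ] <- c(0.1, 0.2)
  se["R", ] <- c(0.3, 0.4)
  panel <- make_panel(m, se)
  out <- apply_proxy_se(panel, c(P = "Q"))
  expect_equal(unname(out$se["P", ]), c(0.1, 0.2))
  # empty map is the identity
  expect_equal(apply_proxy_se(panel, character(0)), panel)
  # proxy itself missing -> error
  se2 <- se; se2["Q", ] <- NA
  expect_error(apply_proxy_se(make_panel(m, se2), c(P = "Q")), "missing SE")
})

test_that("filter_complete drops incomplete genes and their pairs, idempotently", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  m["s2", "g2"] <- NA
  panel <- make_panel(m, abs(m) * 0.1)
  pairs <- data.frame(gene1 = c("g1", "g2"), gene2 = c("g3", "g3"))
  out <- suppressMessages(filter_complete(panel, pairs))
  expect_equal(out$dropped_genes, "g2")
  expect_equal(out$panel$genes, c("g1", "g3"))
  expect_equal(nrow(out$pairs), 1)
  # idempotent
  out2 <- suppressMessages(filter_complete(out$panel, out$pairs))
  expect_equal(out2$panel, out$panel)
  expect_equal(out2$pairs, out$pairs)
  # no missing data is the identity
  panel_ok <- make_panel(matrix(1:4 + 0.5, 2, 2,
                                dimnames = list(c("s1", "s2"),
                                                c("g1", "g2"))),
                         matrix(0.1, 2, 2))
  expect_equal(filter_complete(panel_ok)$panel$genes, c("g1", "g2"))
  # everything missing somewhere -> empty panel with warning
  m_all <- matrix(c(NA, 1, 1, NA), 2, 2,
                  dimnames = list(c("s1", "s2"), c("g1", "g2")))
  expect_warning(res <- filter_complete(make_panel(m_all, m_all * 0)),
                 "all genes")
  expect_length(res$panel$genes, 0)
})

test_that("build_panel standardizes replicates and records missingness", {
  set.seed(8)
  reps <- list(
    s1 = matrix(rlnorm(30), 10, 3,
                dimnames = list(paste0("g", 1:10), NULL)),
    s2 = matrix(rlnorm(30), 10, 3,
                dimnames = list(paste0("g", 1:10), NULL)))
  reps$s2["g4", ] <- 0  # unexpressed gene in species 2
  panel <- build_panel(reps)
  expect_s3_class(panel, "expression_panel")
  expect_equal(dim(panel$mean), c(2, 10))
  expect_true(is.na(panel$mean["s2", "g4"]))
  expect_true(all(panel$se >= 0, na.rm = TRUE))
  expect_equal(unname(panel$n_replicates), c(3L, 3L))
})

test_that("select_timepoints finds mutually correlated columns", {
  set.seed(2)
  base <- rnorm(100)
  mat <- cbind(a = base + rnorm(100, sd = 0.01),
               b = rnorm(100),
               c = base + rnorm(100, sd = 0.01),
               d = base + rnorm(100, sd = 0.01))
  expect_equal(select_timepoints(mat, k = 3, min_cor = 0.9), c(1, 3, 4))
  expect_error(select_timepoints(mat[, 1:2], k = 3), "fewer than")
})

test_that("panels round-trip through TSV", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  panel <- make_panel(m, abs(m) * 0.1)
  fm <- tempfile(fileext = ".tsv"); fs <- tempfile(fileext = ".tsv")
  write_panel(panel, fm, fs)
  back <- read_panel(fm, fs)
  expect_equal(back$mean, panel$mean, tolerance = 1e-9)
  expect_equal(back$se, panel$se, tolerance = 1e-9)
})
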