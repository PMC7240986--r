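#' Per-pair weights from gene appearance counts
#'
#' Genes appearing in many pairs would otherwise dominate group-level
#' statistics. Each pair is weighted by
#' \deqn{w = \frac{1}{2}\left(\frac{1}{N_1} + \frac{1}{N_2}\right),}
#' where \code{N_i} is the number of times gene i appears in the pair set.
#'
#' @param pairs Data frame with columns \code{gene1}, \code{gene2}.
#' @return Numeric vector of weights, one per row of \code{pairs}.
#' @export
pair_weights <- function(pairs) {
  all_genes <- c(pairs$gene1, pairs$gene2)
  counts <- table(all_genes)
  n1 <- as.numeric(counts[pairs$gene1])
  n2 <- as.numeric(counts[pairs$gene2])
  0.5 * (1 / n1 + 1 / n2)
}

#' Weighted Spearman rank correlation with bootstrap inference
#'
#' Ranks both vectors (average ranks for ties) and computes the weighted
#' Pearson correlation of the ranks. With equal weights this reduces exactly
#' to the ordinary Spearman correlation. Confidence intervals are percentile
#' bootstrap over pairs; when \code{pairs} is supplied the weights are
#' recomputed per resample from the appearance counts in that resample. The
#' p-value is the bootstrap inversion: twice the proportion of bootstrap
#' estimates crossing 0, floored at \code{1/B}.
#'
#' @param x,y Numeric vectors, length \code{m >= 4}.
#' @param weights Positive weights (default equal). Ignored when \code{pairs}
#'   is supplied.
#' @param pairs Optional data frame (\code{gene1}, \code{gene2}) from which
#'   weights are derived via [pair_weights()], per resample.
#' @param B Bootstrap replicates (default 2000); \code{B = 0} skips the
#'   bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with \code{rho_s}, \code{ci} (length-2 vector or NULL) and
#'   \code{p} (NULL when \code{B = 0}).
#' @export
weighted_spearman <- function(x, y, weights = NULL, pairs = NULL, B = 2000,
                              conf = 0.95, seed = NULL) {
  m <- length(x)
  if (m < 3) stop("need at least 3 pairs")
  if (length(y) != m) stop("x and y must have equal length")
  if (!is.null(pairs)) weights <- pair_weights(pairs)
  if (is.null(weights)) weights <- rep(1, m)
  if (any(weights <= 0)) stop("weights must be positive")
  rho_s <- weighted_rank_cor(x, y, weights)
  if (B == 0) return(list(rho_s = rho_s, ci = NULL, p = NULL))
  if (!is.null(seed)) set.seed(seed)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(m, m, replace = TRUE)
    wb <- if (!is.null(pairs)) {
      pair_weights(pairs[idx, , drop = FALSE])
    } else {
      weights[idx]
    }
    boot[b] <- weighted_rank_cor(x[idx], y[idx], wb)
  }
  boot <- boot[is.finite(boot)]
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  p <- max(2 * min(mean(boot <= 0), mean(boot >= 0)), 1 / B)
  p <- min(p, 1)
  list(rho_s = rho_s, ci = ci, p = p)
}

# Weighted Pearson correlation of average ranks. Ranks are computed
# unweighted; weights enter only the correlation.
weighted_rank_cor <- function(x, y, w) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("constant ranks")
  w <- w / sum(w)
  mx <- sum(w * rx); my <- sum(w * ry)
  sxy <- sum(w * (rx - mx) * (ry - my))
  sxx <- sum(w * (rx - mx)^2)
  syy <- sum(w * (ry - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

#' One-sample and two-sample tests on fitted correlation distributions
#'
#' For each group, tests whether the mean correlation differs from 0
#' (one-sample t-test with 95\% CI); between groups, Welch's t-test.
#'
#' @param rho_binding,rho_control Numeric vectors of per-pair correlations.
#' @param conf Confidence level (default 0.95).
#' @return A list with \code{binding}, \code{control} (each: mean, ci, p) and
#'   \code{welch} (statistic, p).
#' @export
group_tests <- function(rho_binding, rho_control, conf = 0.95) {
  one <- function(v) {
    if (length(v) < 2) stop("group needs at least 2 values")
    if (stats::sd(v) == 0) stop("zero variance in group; t-test undefined")
    tt <- stats::t.test(v, mu = 0, conf.level = conf)
    list(mean = mean(v), ci = unname(tt$conf.int), p = tt$p.value)
  }
  if (stats::sd(rho_binding) == 0 && stats::sd(rho_control) == 0) {
    stop("zero variance in both groups; Welch test undefined")
  }
  welch <- stats::t.test(rho_binding, rho_control)
  list(binding = one(rho_binding), control = one(rho_control),
       welch = list(statistic = unname(welch$statistic), p = welch$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up q-values, monotone in p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Membership-controlled subset resampling
#'
#' Generates subsets of a pair set in which each gene appears in at most one
#' pair, by greedy randomized selection: shuffle the pairs, accept a pair iff
#' neither gene has been used, stop at \code{max_size}. Used to check whether
#' genes appearing in many pairs bias group-level correlation summaries.
#'
#' @param pairs Data frame with columns \code{gene1}, \code{gene2}.
#' @param values Optional data frame or named list of per-pair statistics
#'   (e.g. columns \code{rho_c}, \code{rho_u}) whose subset means are wanted.
#' @param n_subsets Number of subsets (default 200).
#' @param max_size Maximum pairs per subset (default 200).
#' @param seed Optional integer seed.
#' @return A list with \code{subsets} (list of integer row indices) and
#'   \code{means} (data frame of per-subset means, NULL when \code{values} is
#'   missing).
#' @export
membership_subsets <- function(pairs, values = NULL, n_subsets = 200,
                               max_size = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(pairs)
  subsets <- vector("list", n_subsets)
  for (s in seq_len(n_subsets)) {
    ord <- sample.int(m)
    used <- character(0)
    sel <- integer(0)
    for (k in ord) {
      g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
      if (g1 %in% used || g2 %in% used) next
      sel <- c(sel, k)
      used <- c(used, g1, g2)
      if (length(sel) >= max_size) break
    }
    subsets[[s]] <- sort(sel)
  }
  means <- NULL
  if (!is.null(values)) {
    values <- as.data.frame(values)
    means <- do.call(rbind, lapply(subsets, function(idx) {
      colMeans(values[idx, , drop = FALSE], na.rm = TRUE)
    }))
    means <- as.data.frame(means)
  }
  list(subsets = subsets, means = means)
}
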