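#' Histogram-crossover significance cutoff
#'
#' Compares relative histograms of correlations from a binding and a control
#' group on common bins spanning \[-1, 1\] and returns the left edge of the
#' smallest bin such that the binding group's relative frequency strictly
#' exceeds the control group's in every nonempty bin at or above it. Empty
#' bins (no mass in either group) are skipped when checking the condition.
#' Returns \code{NA} as cutoff when no such bin exists.
#'
#' @param binding_r,control_r Numeric vectors of correlations in \[-1, 1\].
#' @param bin_width Histogram bin width (default 0.05).
#' @return A list of class \code{"crossover_cutoff"} with \code{cutoff}
#'   (numeric or \code{NA}), \code{bin_width} and \code{bin_edges}.
#' @export
crossover_cutoff <- function(binding_r, control_r, bin_width = 0.05) {
  if (length(binding_r) == 0 || length(control_r) == 0) {
    stop("both groups must be nonempty")
  }
  edges <- seq(-1, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin_of <- function(r) pmin(findInterval(r, edges, rightmost.closed = TRUE),
                             length(edges) - 1)
  fb <- tabulate(bin_of(binding_r), nbins = length(edges) - 1) / length(binding_r)
  fc <- tabulate(bin_of(control_r), nbins = length(edges) - 1) / length(control_r)
  nonempty <- fb > 0 | fc > 0
  ok <- fb > fc  # strict dominance, checked on nonempty bins only
  cutoff <- NA_real_
  # smallest bin b* with dominance in all nonempty bins >= b*
  holds <- TRUE
  candidate <- NA_integer_
  for (b in rev(seq_along(ok))) {
    if (nonempty[b] && !ok[b]) break
    if (nonempty[b]) candidate <- b
  }
  if (!is.na(candidate)) cutoff <- edges[candidate]
  structure(list(cutoff = cutoff, bin_width = bin_width, bin_edges = edges),
            class = "crossover_cutoff")
}

#' Classify correlations against a crossover cutoff
#'
#' Pairs with correlation at or above the cutoff are called coevolving
#' (inclusive, since the cutoff is a bin left edge). A missing cutoff yields
#' all-false calls with a warning.
#'
#' @param test_r Numeric vector of correlations.
#' @param cutoff A \code{"crossover_cutoff"} object or numeric scalar.
#' @return Logical vector of calls.
#' @export
crossover_classify <- function(test_r, cutoff) {
  if (inherits(cutoff, "crossover_cutoff")) cutoff <- cutoff$cutoff
  if (is.na(cutoff)) {
    warning("no crossover cutoff found; no pairs called")
    return(rep(FALSE, length(test_r)))
  }
  test_r >= cutoff
}

#' Randomization p-value against a null pool of correlations
#'
#' Draws \code{n_rand} correlations from the null pool (with replacement) and
#' counts how many strictly exceed the target correlation; the p-value is
#' \code{(k + 1) / (n_rand + 1)}, which avoids zero.
#'
#' @param r_target Numeric scalar, the pair's correlation.
#' @param null_pool_r Numeric vector of null (control) correlations.
#' @param n_rand Number of random draws (default 1000).
#' @param seed Optional integer seed.
#' @return A list with \code{k_greater}, \code{p_value} and \code{n_rand}.
#' @export
randomization_p <- function(r_target, null_pool_r, n_rand = 1000,
                            seed = NULL) {
  if (length(null_pool_r) == 0) stop("empty null pool")
  if (!is.null(seed)) set.seed(seed)
  draws <- sample(null_pool_r, n_rand, replace = TRUE)
  k <- sum(draws > r_target)
  list(k_greater = k, p_value = (k + 1) / (n_rand + 1), n_rand = n_rand)
}

# Vectorized randomization p-values for many targets against one pool,
# optionally excluding pool pairs that share a gene with the target
# (leakage guard). pool_genes: 2-column character matrix aligned to the pool.
randomization_p_all <- function(r_targets, null_pool_r, n_rand = 1000,
                                target_genes = NULL, pool_genes = NULL) {
  m <- length(r_targets)
  p <- numeric(m)
  if (is.null(target_genes) || is.null(pool_genes)) {
    draws <- matrix(sample(null_pool_r, n_rand * m, replace = TRUE), n_rand, m)
    k <- colSums(draws > rep(r_targets, each = n_rand))
    return((k + 1) / (n_rand + 1))
  }
  for (i in seq_len(m)) {
    keep <- !(pool_genes[, 1] %in% target_genes[i, ] |
                pool_genes[, 2] %in% target_genes[i, ])
    pool <- null_pool_r[keep]
    if (length(pool) == 0) pool <- null_pool_r
    draws <- sample(pool, n_rand, replace = TRUE)
    p[i] <- (sum(draws > r_targets[i]) + 1) / (n_rand + 1)
  }
  p
}

#' Empirically calibrate a p-value cutoff to a target FDR
#'
#' Scans the observed p-values and returns the largest cutoff \code{tau} such
#' that, calling every pair with \code{p <= tau} and counting control calls
#' as false positives, the empirical false discovery rate
#' \code{control calls / total calls} does not exceed \code{target_fdr}.
#' When no cutoff qualifies, returns the minimal observed p minus a small
#' epsilon (so that nothing is called).
#'
#' @param p_binding,p_control Numeric vectors of p-values.
#' @param target_fdr Target false discovery rate (default 0.05).
#' @return Numeric scalar cutoff.
#' @export
calibrate_cutoff_fdr <- function(p_binding, p_control, target_fdr = 0.05) {
  if (length(p_binding) == 0 || length(p_control) == 0) {
    stop("both p-value vectors must be nonempty")
  }
  taus <- sort(unique(c(p_binding, p_control)))
  best <- NA_real_
  for (tau in taus) {
    calls_b <- sum(p_binding <= tau)
    calls_c <- sum(p_control <= tau)
    total <- calls_b + calls_c
    if (total == 0) next
    if (calls_c / total <= target_fdr) best <- tau
  }
  if (is.na(best)) best <- min(taus) - 1e-12
  best
}

#' Stratified train/test split of binding and control pairs
#'
#' Splits each group independently into training and test fractions, for
#' learning the crossover cutoff on one part and evaluating on the held-out
#' part.
#'
#' @param n_binding,n_control Group sizes.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Optional integer seed.
#' @return A list with logical vectors \code{binding_train} and
#'   \code{control_train}.
#' @export
split_train_test <- function(n_binding, n_control, train_frac = 0.8,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bt <- rep(FALSE, n_binding)
  bt[sample.int(n_binding, round(train_frac * n_binding))] <- TRUE
  ct <- rep(FALSE, n_control)
  ct[sample.int(n_control, round(train_frac * n_control))] <- TRUE
  list(binding_train = bt, control_train = ct)
}
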