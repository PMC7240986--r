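#' Confusion-matrix rates for a detection method
#'
#' @param tp,fn,fp,tn Nonnegative counts.
#' @return A list with \code{tpr}, \code{fpr}, \code{fdr} (0 when no calls)
#'   and \code{accuracy}.
#' @export
confusion_rates <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  total <- tp + fn + fp + tn
  if (total == 0) stop("all counts are zero")
  list(tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       accuracy = (tp + tn) / total)
}

#' Run one detection method on fitted pairs
#'
#' Applies one of the four benchmarked procedures to a table of per-pair
#' fits (from [fit_pairs()]) and returns boolean calls:
#' \describe{
#'   \item{pcm_lrt}{Likelihood-ratio test of the bivariate Brownian-Motion
#'     model, BH-corrected over the supplied pairs, called at q < alpha.}
#'   \item{pearson_test}{Two-sided t-test on the uncorrected Pearson
#'     correlation, BH-corrected, called at q < alpha.}
#'   \item{crossover}{Histogram-crossover cutoff learned on a stratified
#'     80/20 train split of binding vs control correlations; held-out pairs
#'     at or above the cutoff are called. Returns calls for test pairs and a
#'     \code{test_set} indicator.}
#'   \item{randomization}{Per-pair randomization p-value against the control
#'     correlation pool (pairs sharing a gene with the target excluded),
#'     with the p cutoff calibrated so the empirical FDR is at most
#'     \code{target_fdr}.}
#' }
#'
#' @param method One of \code{"pcm_lrt"}, \code{"pearson_test"},
#'   \code{"crossover"}, \code{"randomization"}.
#' @param fits Data frame from [fit_pairs()] including a \code{group} column
#'   with values \code{"binding"}/\code{"control"}.
#' @param statistic \code{"rho_c"} or \code{"rho_u"}: correlation used by the
#'   crossover and randomization procedures.
#' @param alpha Significance level for the BH-based methods (default 0.05).
#' @param bin_width Crossover histogram bin width (default 0.05).
#' @param train_frac Crossover training fraction (default 0.8).
#' @param n_rand Randomization draws per pair (default 1000).
#' @param target_fdr Calibration target for the randomization cutoff
#'   (default 0.05).
#' @param allow_shared_genes If \code{TRUE}, the randomization null pool is
#'   not purged of pairs sharing a gene with the target (default
#'   \code{FALSE}).
#' @param seed Optional integer seed (split and draws).
#' @return A list with logical vector \code{calls} (NA outside the evaluated
#'   subset for \code{crossover}) and, for crossover, \code{test_set}.
#' @export
run_method <- function(method, fits,
                       statistic = c("rho_c", "rho_u"), alpha = 0.05,
                       bin_width = 0.05, train_frac = 0.8, n_rand = 1000,
                       target_fdr = 0.05, allow_shared_genes = FALSE,
                       seed = NULL) {
  statistic <- match.arg(statistic)
  is_b <- fits$group == "binding"
  r <- fits[[statistic]]
  if (!is.null(seed)) set.seed(seed)
  if (method == "pcm_lrt") {
    q <- bh_adjust(fits$p)
    return(list(calls = q < alpha))
  }
  if (method == "pearson_test") {
    q <- bh_adjust(fits$p_u)
    return(list(calls = q < alpha))
  }
  if (method == "crossover") {
    sp <- split_train_test(sum(is_b), sum(!is_b), train_frac)
    train <- logical(nrow(fits))
    train[which(is_b)[sp$binding_train]] <- TRUE
    train[which(!is_b)[sp$control_train]] <- TRUE
    cut <- crossover_cutoff(r[is_b & train], r[!is_b & train], bin_width)
    calls <- rep(NA, nrow(fits))
    calls[!train] <- suppressWarnings(crossover_classify(r[!train], cut))
    return(list(calls = calls, test_set = !train, cutoff = cut$cutoff))
  }
  if (method == "randomization") {
    pool <- r[!is_b]
    genes <- as.matrix(fits[, c("gene1", "gene2")])
    p <- randomization_p_all(
      r, pool, n_rand = n_rand,
      target_genes = if (allow_shared_genes) NULL else genes,
      pool_genes = if (allow_shared_genes) NULL else genes[!is_b, , drop = FALSE])
    tau <- calibrate_cutoff_fdr(p[is_b], p[!is_b], target_fdr)
    return(list(calls = p <= tau, p_values = p, cutoff = tau))
  }
  stop("unknown method: ", method)
}

#' Compare detection methods on labeled simulated pairs
#'
#' The method-comparison harness: per repetition, the control pairs are
#' subsampled to the size of the binding set (so accuracy is not skewed by
#' group imbalance), each method is run on the pooled set, and TPR, FPR, FDR
#' and accuracy are computed against the truth labels. Means and standard
#' deviations over repetitions are reported.
#'
#' @param fits Data frame from [fit_pairs()] on simulated data, with
#'   \code{group} and \code{truth} columns.
#' @param methods Character vector of method/statistic combinations as
#'   \code{"method:statistic"} (e.g. \code{"crossover:rho_u"}); plain method
#'   names default to \code{rho_c} for \code{pcm_lrt} and crossover /
#'   randomization, \code{rho_u} for \code{pearson_test}.
#' @param n_repetitions Number of assessment repetitions (default 100).
#' @param seed Integer seed; repetition r uses \code{seed + r}.
#' @param ... Passed to [run_method()].
#' @return A data frame of class \code{"method_performance"}: one row per
#'   method with means and sds of tpr, fpr, fdr, accuracy.
#' @export
assess <- function(fits, methods = c("pcm_lrt:rho_c", "pearson_test:rho_u",
                                     "crossover:rho_c", "crossover:rho_u",
                                     "randomization:rho_c",
                                     "randomization:rho_u"),
                   n_repetitions = 100, seed = 1, ...) {
  if (!all(c("group", "truth") %in% names(fits))) {
    stop("fits must carry 'group' and 'truth' columns")
  }
  is_b <- fits$group == "binding"
  n_b <- sum(is_b)
  if (n_b == 0) stop("binding set is empty; TPR undefined")
  if (sum(!is_b) < n_b) stop("control set smaller than binding set")
  parse_m <- function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2) return(parts)
    c(parts, if (parts == "pearson_test") "rho_u" else "rho_c")
  }
  specs <- lapply(methods, parse_m)
  acc <- array(NA_real_, c(length(specs), n_repetitions, 4),
               dimnames = list(methods, NULL,
                               c("tpr", "fpr", "fdr", "accuracy")))
  for (r in seq_len(n_repetitions)) {
    set.seed(seed + r)
    ctrl_idx <- sample(which(!is_b), n_b)
    rows <- c(which(is_b), ctrl_idx)
    sub <- fits[rows, , drop = FALSE]
    for (i in seq_along(specs)) {
      res <- run_method(specs[[i]][1], sub, statistic = specs[[i]][2],
                        seed = seed * 1000 + r, ...)
      eval_set <- if (is.null(res$test_set)) rep(TRUE, nrow(sub)) else res$test_set
      calls <- res$calls[eval_set]
      calls[is.na(calls)] <- FALSE
      truth <- sub$truth[eval_set]
      cr <- confusion_rates(sum(calls & truth), sum(!calls & truth),
                            sum(calls & !truth), sum(!calls & !truth))
      acc[i, r, ] <- unlist(cr)
    }
  }
  out <- data.frame(
    method = vapply(specs, `[`, "", 1),
    statistic = vapply(specs, `[`, "", 2),
    tpr = apply(acc[, , "tpr", drop = FALSE], 1, mean),
    tpr_sd = apply(acc[, , "tpr", drop = FALSE], 1, stats::sd),
    fpr = apply(acc[, , "fpr", drop = FALSE], 1, mean),
    fpr_sd = apply(acc[, , "fpr", drop = FALSE], 1, stats::sd),
    fdr = apply(acc[, , "fdr", drop = FALSE], 1, mean),
    fdr_sd = apply(acc[, , "fdr", drop = FALSE], 1, stats::sd),
    accuracy = apply(acc[, , "accuracy", drop = FALSE], 1, mean),
    accuracy_sd = apply(acc[, , "accuracy", drop = FALSE], 1, stats::sd),
    n_repetitions = n_repetitions,
    row.names = NULL)
  class(out) <- c("method_performance", "data.frame")
  out
}

#' Simulate, fit and assess in one call
#'
#' Composes the benchmark pipeline: generate labeled binding/control pair
#' sets under bivariate Brownian Motion ([generate_pair_sets()]), fit the
#' model to every pair ([fit_pairs()]), and compare detection methods over
#' repeated assessments ([assess()]).
#'
#' @param config A \code{"sim_config"}; its seed drives all randomness.
#' @param methods,n_repetitions Passed to [assess()].
#' @param ... Passed to [run_method()] via [assess()].
#' @return A list with \code{sim}, \code{fits} and \code{performance}.
#' @export
run_benchmark <- function(config = sim_config(),
                          methods = c("pcm_lrt:rho_c", "pearson_test:rho_u",
                                      "crossover:rho_u",
                                      "randomization:rho_u"),
                          n_repetitions = 20, ...) {
  sim <- generate_pair_sets(config)
  fits <- fit_pairs(sim$panel, sim$pairs, sim$tree)
  perf <- assess(fits, methods = methods, n_repetitions = n_repetitions,
                 seed = config$seed, ...)
  list(sim = sim, fits = fits, performance = perf)
}

#' @export
print.method_performance <- function(x, digits = 3, ...) {
  cat("Method performance over", x$n_repetitions[1], "repetitions\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df)
  invisible(x)
}
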