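#' Phylogenetic independent contrasts with their standard deviations
#'
#' Computes Felsenstein's standardized contrasts by the pruning algorithm: at
#' each internal node the contrast is the difference of the two daughter
#' values divided by the square root of the summed (adjusted) daughter branch
#' lengths, the node value is the weighted average of the daughters, and the
#' parent branch is lengthened by the harmonic contribution
#' \code{bL * bR / (bL + bR)}. Under Brownian Motion the standardized
#' contrasts are i.i.d. normal.
#'
#' Multifurcations are resolved deterministically (in tip order) with
#' zero-length branches before computing contrasts.
#'
#' @param tree A rooted \code{"phylo"} object with branch lengths.
#' @param x Named numeric vector of tip values (complete).
#' @return A list with \code{contrasts} (standardized contrasts) and
#'   \code{sds} (square roots of the expected contrast variances, in
#'   time^(1/2) units), each of length \code{n - 1}.
#' @export
pic_contrasts <- function(tree, x) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (!is.null(names(x))) x <- x[tree$tip.label]
  if (anyNA(x)) stop("missing trait data; contrasts require complete data")
  pc <- ape::pic(x, tree, var.contrasts = TRUE)
  list(contrasts = unname(pc[, 1]), sds = unname(sqrt(pc[, 2])))
}

#' Screen a trait for violation of the Brownian-Motion assumption
#'
#' Correlates the (absolute) standardized contrasts with their standard
#' deviations; under Brownian Motion the standardized contrasts are
#' identically distributed whatever the branch lengths, so a significant
#' correlation indicates model violation. The absolute-value form is
#' the standard diagnostic; \code{diagnostic = "raw"} uses the signed
#' contrasts instead.
#'
#' @param tree A rooted \code{"phylo"} object.
#' @param x Named numeric tip values, \code{n >= 4}.
#' @param diagnostic \code{"abs"} (default) or \code{"raw"}.
#' @param alpha Significance level for the violation flag (default 0.05).
#' @return A list with \code{r}, \code{p}, \code{violated} and
#'   \code{testable}. Traits with zero variance in either vector are flagged
#'   untestable and not violated.
#' @export
bm_violation_test <- function(tree, x, diagnostic = c("abs", "raw"),
                              alpha = 0.05) {
  diagnostic <- match.arg(diagnostic)
  if (length(tree$tip.label) < 4) stop("need at least 4 species")
  pc <- pic_contrasts(tree, x)
  v <- if (diagnostic == "abs") abs(pc$contrasts) else pc$contrasts
  if (stats::sd(v) == 0 || stats::sd(pc$sds) == 0) {
    return(list(r = NA_real_, p = NA_real_, violated = FALSE,
                testable = FALSE))
  }
  ct <- stats::cor.test(v, pc$sds)
  list(r = unname(ct$estimate), p = ct$p.value,
       violated = ct$p.value < alpha, testable = TRUE)
}

#' Drop gene pairs containing a gene that violates the BM assumption
#'
#' Each gene is screened once with [bm_violation_test()] on the full species
#' set; pairs containing a violating gene are removed. Disable the filter to
#' reproduce unfiltered variants of the analysis.
#'
#' @param panel An \code{"expression_panel"} with complete data.
#' @param tree A rooted \code{"phylo"} object matching the panel's species.
#' @param pairs Data frame with columns \code{gene1}, \code{gene2}.
#' @param enabled Logical; if \code{FALSE} the pairs are returned unchanged.
#' @param diagnostic Passed to [bm_violation_test()].
#' @return A list with \code{pairs}, \code{report} (one row per tested gene:
#'   gene, r, p, violated) and \code{violating_genes}.
#' @export
filter_bm <- function(panel, tree, pairs, enabled = TRUE,
                      diagnostic = c("abs", "raw")) {
  diagnostic <- match.arg(diagnostic)
  genes <- unique(c(pairs$gene1, pairs$gene2))
  sp <- tree$tip.label
  report <- data.frame(gene = genes, r = NA_real_, p = NA_real_,
                       violated = FALSE)
  for (i in seq_along(genes)) {
    x <- panel$mean[sp, genes[i]]
    res <- bm_violation_test(tree, x, diagnostic = diagnostic)
    report$r[i] <- res$r
    report$p[i] <- res$p
    report$violated[i] <- isTRUE(res$violated)
  }
  bad <- report$gene[report$violated]
  if (!enabled) {
    return(list(pairs = pairs, report = report, violating_genes = bad))
  }
  keep <- !(pairs$gene1 %in% bad | pairs$gene2 %in% bad)
  message(sum(!keep), " of ", length(keep), " pairs dropped (BM violation); ",
          length(bad), " genes flagged")
  list(pairs = pairs[keep, , drop = FALSE], report = report,
       violating_genes = bad)
}
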