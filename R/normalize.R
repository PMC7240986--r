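#' Standardize one RNA-seq sample to a standard lognormal scale
#'
#' Transforms a vector of TPM values so that the log values of the expressed
#' genes have sample mean 0 and sample standard deviation 1, i.e.
#' \code{ln(X) ~ N(0, 1)} empirically. Genes with TPM equal to 0 have an
#' undefined log and are returned as \code{NA}; they are excluded from the
#' centering and scaling.
#'
#' @param tpm Named nonnegative numeric vector of TPM values (one sample).
#' @return Numeric vector of the same length and names; \code{NA} where
#'   \code{tpm == 0}.
#' @export
standardize_sample <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be nonnegative")
  pos <- which(!is.na(tpm) & tpm > 0)
  if (length(pos) < 3) stop("need at least 3 genes with TPM > 0")
  lg <- log(tpm[pos])
  s <- stats::sd(lg)
  if (s == 0) stop("zero variance among expressed genes; cannot standardize")
  z <- rep(NA_real_, length(tpm))
  names(z) <- names(tpm)
  z[pos] <- (lg - mean(lg)) / s
  z
}

#' Summarize normalized replicates into per-gene mean and standard error
#'
#' @param z A genes x replicates numeric matrix of normalized values
#'   (\code{NA} = missing), or a list of equal-length named vectors.
#' @return A list with numeric vectors \code{mean}, \code{se} and integer
#'   vector \code{m} (replicates observed per gene). \code{se} is the sample
#'   standard deviation over observed replicates divided by \code{sqrt(m)} and
#'   is \code{NA} when \code{m == 1}; \code{mean} is \code{NA} when a gene is
#'   unobserved in all replicates.
#' @export
summarize_replicates <- function(z) {
  if (is.list(z) && !is.matrix(z)) {
    if (length(z) == 0) stop("no replicates supplied")
    z <- do.call(cbind, z)
  }
  z <- as.matrix(z)
  if (ncol(z) == 0) stop("no replicates supplied")
  m <- rowSums(!is.na(z))
  mu <- ifelse(m > 0, rowMeans(z, na.rm = TRUE), NA_real_)
  sdv <- apply(z, 1, function(v) stats::sd(v[!is.na(v)]))
  se <- ifelse(m > 1, sdv / sqrt(m), NA_real_)
  list(mean = stats::setNames(as.numeric(mu), rownames(z)),
       se = stats::setNames(as.numeric(se), rownames(z)),
       m = stats::setNames(as.integer(m), rownames(z)))
}

#' Construct an expression panel from per-species replicate tables
#'
#' Each species contributes a genes x replicates TPM matrix. Every replicate
#' column is standardized with [standardize_sample()] (set
#' \code{standardized = TRUE} if the values are already on the normalized log
#' scale) and summarized with [summarize_replicates()]. The panel stores
#' species x gene matrices of means and standard errors over the union of
#' gene names, with \code{NA} marking missing data.
#'
#' @param replicates Named list (one element per species) of genes x
#'   replicates numeric matrices with gene rownames.
#' @param standardized Logical; if \code{FALSE} (default) columns are TPM and
#'   are log-standardized first.
#' @return An object of class \code{"expression_panel"}: a list with
#'   \code{species}, \code{genes}, \code{mean}, \code{se} (species x gene
#'   matrices) and \code{n_replicates} (named integer vector).
#' @export
build_panel <- function(replicates, standardized = FALSE) {
  if (length(replicates) == 0 || is.null(names(replicates))) {
    stop("'replicates' must be a named list of matrices, one per species")
  }
  species <- names(replicates)
  genes <- sort(unique(unlist(lapply(replicates, rownames))))
  if (length(genes) == 0) stop("replicate matrices must have gene rownames")
  mean_m <- matrix(NA_real_, length(species), length(genes),
                   dimnames = list(species, genes))
  se_m <- mean_m
  n_rep <- stats::setNames(integer(length(species)), species)
  for (sp in species) {
    mat <- as.matrix(replicates[[sp]])
    if (!standardized) mat <- apply(mat, 2, standardize_sample)
    smry <- summarize_replicates(mat)
    mean_m[sp, rownames(mat)] <- smry$mean
    se_m[sp, rownames(mat)] <- smry$se
    n_rep[sp] <- ncol(mat)
  }
  new_expression_panel(species, genes, mean_m, se_m, n_rep)
}

#' @keywords internal
new_expression_panel <- function(species, genes, mean_m, se_m, n_rep) {
  stopifnot(identical(dim(mean_m), dim(se_m)))
  if (any(se_m < 0, na.rm = TRUE)) stop("standard errors must be nonnegative")
  structure(list(species = species, genes = genes, mean = mean_m, se = se_m,
                 n_replicates = n_rep),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("Expression panel:", length(x$species), "species x",
      length(x$genes), "genes\n")
  cat("  missing means:", sum(is.na(x$mean)), " missing SEs:",
      sum(is.na(x$se)), "\n")
  invisible(x)
}

#' Fill missing standard errors from a proxy species
#'
#' Species whose RNA-seq data lack replicates have no standard-error
#' estimates; a closely-related proxy species' gene-wise standard errors are
#' used instead.
#'
#' @param panel An \code{"expression_panel"}.
#' @param proxy_map Named character vector mapping species with missing SEs
#'   to proxy species (\code{c(target = "proxy")}).
#' @return The panel with SE rows filled in.
#' @export
apply_proxy_se <- function(panel, proxy_map) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(proxy_map) == 0) return(panel)
  for (target in names(proxy_map)) {
    proxy <- proxy_map[[target]]
    if (!target %in% panel$species) stop("unknown species: ", target)
    if (!proxy %in% panel$species) stop("unknown proxy species: ", proxy)
    need <- is.na(panel$se[target, ]) & !is.na(panel$mean[target, ])
    if (!any(need)) next
    donor <- panel$se[proxy, need]
    if (any(is.na(donor))) {
      stop("proxy species '", proxy, "' has missing SE for ",
           sum(is.na(donor)), " genes needed by '", target, "'")
    }
    panel$se[target, need] <- donor
  }
  panel
}

#' Restrict a panel (and pair list) to genes observed in every species
#'
#' Genes with missing data in any species — no ortholog or no expression
#' estimate — are excluded from further analysis, and gene pairs touching an
#' excluded gene are dropped.
#'
#' @param panel An \code{"expression_panel"}.
#' @param pairs Optional data frame with columns \code{gene1}, \code{gene2}.
#' @return A list with elements \code{panel}, \code{pairs} (or \code{NULL}),
#'   and \code{dropped_genes}.
#' @export
filter_complete <- function(panel, pairs = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  complete <- colSums(is.na(panel$mean)) == 0
  dropped <- panel$genes[!complete]
  if (all(!complete)) warning("all genes have missing data; panel is empty")
  panel$mean <- panel$mean[, complete, drop = FALSE]
  panel$se <- panel$se[, complete, drop = FALSE]
  panel$genes <- panel$genes[complete]
  if (!is.null(pairs)) {
    keep <- !(pairs$gene1 %in% dropped | pairs$gene2 %in% dropped)
    message(sum(!keep), " of ", length(keep),
            " pairs dropped (missing data); ", length(dropped),
            " genes excluded")
    pairs <- pairs[keep, , drop = FALSE]
  }
  list(panel = panel, pairs = pairs, dropped_genes = dropped)
}

#' Select well-correlated replicate columns from a time-course experiment
#'
#' Picks the first \code{k} columns that are mutually correlated above a
#' Pearson threshold, emulating the curation of time-course RNA-seq data into
#' pseudo-replicates.
#'
#' @param mat Genes x samples numeric matrix.
#' @param k Number of columns to select (default 3).
#' @param min_cor Pearson correlation threshold (default 0.98).
#' @return Column indices of the selected samples.
#' @export
select_timepoints <- function(mat, k = 3, min_cor = 0.98) {
  mat <- as.matrix(mat)
  if (ncol(mat) < k) stop("fewer than ", k, " samples available")
  cc <- stats::cor(mat, use = "pairwise.complete.obs")
  for (start in seq_len(ncol(mat))) {
    sel <- start
    for (j in seq_len(ncol(mat))[-start]) {
      if (all(cc[j, sel] > min_cor)) sel <- c(sel, j)
      if (length(sel) == k) return(sort(sel))
    }
  }
  stop("no set of ", k, " mutually correlated samples at threshold ", min_cor)
}

#' Read an expression panel from mean/SE TSV matrices
#'
#' @param mean_path,se_path TSV files, rows = species (first column
#'   \code{species}), remaining columns = genes. \code{se_path} may be
#'   \code{NULL}, leaving SEs missing.
#' @return An \code{"expression_panel"}.
#' @export
read_panel <- function(mean_path, se_path = NULL) {
  read_one <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  mean_m <- read_one(mean_path)
  se_m <- if (is.null(se_path)) {
    matrix(NA_real_, nrow(mean_m), ncol(mean_m), dimnames = dimnames(mean_m))
  } else {
    read_one(se_path)
  }
  if (!identical(dimnames(mean_m), dimnames(se_m))) {
    stop("mean and SE matrices must share species and gene names")
  }
  new_expression_panel(rownames(mean_m), colnames(mean_m), mean_m, se_m,
                       stats::setNames(rep(NA_integer_, nrow(mean_m)),
                                       rownames(mean_m)))
}

#' Write an expression panel to mean/SE TSV matrices
#'
#' @param panel An \code{"expression_panel"}.
#' @param mean_path,se_path Output file paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, mean_path, se_path) {
  write_one <- function(m, p) {
    df <- data.frame(species = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(panel$mean, mean_path)
  write_one(panel$se, se_path)
  invisible(panel)
}
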