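#' Markov clustering (MCL) of a weighted network
#'
#' Standard MCL: add self-loops, column-normalize the weighted adjacency
#' matrix, then alternate expansion (matrix squaring) and inflation
#' (elementwise power followed by column renormalization), pruning small
#' entries, until the matrix is (numerically) stationary. Clusters are the
#' connected components of the converged flow matrix. The algorithm is
#' deterministic.
#'
#' @param net A \code{"weighted_network"} (see [as_weighted_network()]), or a
#'   data frame with columns \code{gene1}, \code{gene2}, \code{weight}.
#' @param inflation Inflation exponent (default 2).
#' @param expansion Expansion power (default 2).
#' @param max_iter Maximum iterations (default 100).
#' @param prune Entries below this value are zeroed each iteration
#'   (default 1e-5).
#' @param tol Convergence tolerance on the max absolute change (default 1e-6).
#' @param self_loop Self-loop weight added to the (rescaled) adjacency
#'   (default 1).
#' @return A named integer vector mapping every node to a module id
#'   (1-based, ordered by decreasing module size).
#' @export
mcl <- function(net, inflation = 2, expansion = 2, max_iter = 100,
                prune = 1e-5, tol = 1e-6, self_loop = 1) {
  net <- as_weighted_network(net)
  nodes <- net$nodes
  k <- length(nodes)
  if (k == 0) stop("empty network")
  A <- matrix(0, k, k, dimnames = list(nodes, nodes))
  w <- net$edges$weight / max(net$edges$weight)  # rescale to (0, 1]
  i <- match(net$edges$gene1, nodes)
  j <- match(net$edges$gene2, nodes)
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  diag(A) <- self_loop
  normalize <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps),
                                 "/")
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    M2 <- M
    for (e in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  g <- igraph::graph_from_adjacency_matrix((M > 0) | (t(M) > 0),
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  stats::setNames(as.integer(relabel[as.character(comp)]), nodes)
}

#' Coerce an edge list to a weighted network
#'
#' @param x A data frame with columns \code{gene1}, \code{gene2},
#'   \code{weight} (positive), or an existing \code{"weighted_network"}.
#' @return A \code{"weighted_network"}: list with \code{nodes} and
#'   \code{edges}. Self-loops are rejected.
#' @export
as_weighted_network <- function(x) {
  if (inherits(x, "weighted_network")) return(x)
  x <- as.data.frame(x)
  stopifnot(all(c("gene1", "gene2", "weight") %in% names(x)))
  if (any(x$weight <= 0)) stop("edge weights must be positive")
  if (any(x$gene1 == x$gene2)) stop("self-loops are not allowed in input")
  nodes <- sort(unique(c(x$gene1, x$gene2)))
  structure(list(nodes = nodes, edges = x), class = "weighted_network")
}

#' Remove phylogenetic structure from a species x traits matrix
#'
#' With the species covariance \code{C = U D U'}, returns
#' \code{D^(-1/2) U' (X - 1 theta')}, where \code{theta} is the GLS root
#' estimate per trait. Under Brownian Motion the transformed rows are
#' exchangeable (i.i.d. normal with covariance equal to the evolutionary
#' rate matrix), so permutation tests on them are valid.
#'
#' @param X Species x traits numeric matrix (rows ordered as \code{C}).
#' @param C Species covariance matrix from [tree_vcv()].
#' @return The transformed species x traits matrix.
#' @export
phylo_transform <- function(X, C) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(nrow(C) == n)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) <= 1e-10 * max(eg$values)) {
    stop("species covariance matrix is singular")
  }
  Cinv_one <- eg$vectors %*% (t(eg$vectors) %*% rep(1, n) / eg$values)
  theta <- colSums(Cinv_one[, 1] * X) / sum(Cinv_one)
  Xc <- sweep(X, 2, theta)
  diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% Xc
}

#' Phylogenetically-corrected covariance-ratio modularity test
#'
#' Quantifies whether trait covariation is stronger within predefined modules
#' than between them. For modules a and b the pairwise ratio is
#' \deqn{CR_{ab} = \|S_{ab}\|_F / \sqrt{\|S_{aa}^\circ\|_F\,\|S_{bb}^\circ\|_F},}
#' where \code{S} is the trait covariance matrix of the (phylogenetically
#' transformed) data and the within-block diagonals are zeroed; the overall
#' statistic is the mean over module pairs. A value of 1 means between-module
#' covariance equals within-module covariance; smaller values mean more
#' modular structure. Significance is a one-sided permutation test toward
#' modularity: module labels are shuffled across traits and the p-value is
#' the add-one-corrected proportion of permutations with CR at or below the
#' observed value.
#'
#' @param X Transformed species x traits matrix (see [phylo_transform()]);
#'   column names identify traits.
#' @param modules Named vector mapping trait names (or positions) to module
#'   ids.
#' @param n_perm Number of permutations (default 999).
#' @param min_size Minimum module size; smaller modules are dropped
#'   (default 15).
#' @param seed Optional integer seed.
#' @return A list of class \code{"cr_test"} with \code{cr}, \code{p_value},
#'   \code{n_permutations}, \code{pairwise} (matrix of pairwise CRs) and
#'   \code{modules_used}.
#' @export
covariance_ratio <- function(X, modules, n_perm = 999, min_size = 15,
                             seed = NULL) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(names(modules))) {
    modules <- modules[colnames(X)]
  }
  modules <- as.vector(modules)
  if (length(modules) != ncol(X)) stop("one module id per trait is required")
  keep_mods <- names(which(table(modules) >= max(min_size, 2)))
  sel <- modules %in% keep_mods
  if (length(keep_mods) < 2) {
    stop("need at least 2 modules of size >= ", max(min_size, 2))
  }
  X <- X[, sel, drop = FALSE]
  modules <- modules[sel]
  S <- stats::cov(X)
  obs <- cr_statistic(S, modules)
  if (!is.null(seed)) set.seed(seed)
  k <- length(modules)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm[b] <- cr_statistic(S, modules[sample.int(k)])$cr
  }
  p <- (1 + sum(perm <= obs$cr)) / (n_perm + 1)
  structure(list(cr = obs$cr, p_value = p, n_permutations = n_perm,
                 pairwise = obs$pairwise, modules_used = keep_mods),
            class = "cr_test")
}

cr_statistic <- function(S, modules) {
  ids <- unique(modules)
  nm <- length(ids)
  fro <- function(M) sqrt(sum(M^2))
  within <- numeric(nm)
  for (a in seq_len(nm)) {
    Sa <- S[modules == ids[a], modules == ids[a], drop = FALSE]
    diag(Sa) <- 0
    within[a] <- fro(Sa)
  }
  pw <- matrix(NA_real_, nm, nm, dimnames = list(ids, ids))
  vals <- c()
  for (a in seq_len(nm - 1)) {
    for (b in seq((a + 1), nm)) {
      Sab <- S[modules == ids[a], modules == ids[b], drop = FALSE]
      cr <- fro(Sab) / sqrt(within[a] * within[b])
      pw[a, b] <- pw[b, a] <- cr
      vals <- c(vals, cr)
    }
  }
  list(cr = mean(vals), pairwise = pw)
}

#' @export
print.cr_test <- function(x, ...) {
  cat(sprintf("Covariance Ratio = %.4f, p = %.4g (%d permutations, %d modules)\n",
              x$cr, x$p_value, x$n_permutations, length(x$modules_used)))
  invisible(x)
}

#' Read a weighted edge list from TSV
#' @param path TSV with columns gene1, gene2, weight.
#' @return A \code{"weighted_network"}.
#' @export
read_network_tsv <- function(path) {
  as_weighted_network(utils::read.delim(path, stringsAsFactors = FALSE))
}
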